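// Triplex TFO/TTS scan: motif-constrained ungapped matching of an RNA
// against the purine strand of duplex DNA under Hoogsteen pairing rules,
// with error-rate, consecutive-error, guanine-content and length
// constraints. Reports maximal matches (not extendable by one base on
// either side without violating a constraint).

#include <Rcpp.h>
#include <set>
#include <tuple>
using namespace Rcpp;

namespace {

const int BIG = 1 << 28;

char comp(char c) {
  switch (c) {
    case 'A': return 'T';
    case 'C': return 'G';
    case 'G': return 'C';
    case 'T': return 'A';
    default:  return 'N';
  }
}

std::string revcomp(const std::string &s) {
  std::string r(s.rbegin(), s.rend());
  for (auto &c : r) c = comp(c);
  return r;
}

// Hoogsteen triplet rules; rna side is DNA-alphabet (U already mapped to T)
inline bool hoogsteen(char rna, char pur, int motif) {
  // motif: 0 = pyrimidine (U.A, C.G), 1 = purine (A.A, G.G),
  //        2 = mixed (U.A, G.G)
  switch (motif) {
    case 0: return (rna == 'T' && pur == 'A') || (rna == 'C' && pur == 'G');
    case 1: return (rna == 'A' && pur == 'A') || (rna == 'G' && pur == 'G');
    default: return (rna == 'T' && pur == 'A') || (rna == 'G' && pur == 'G');
  }
}

struct Rec {
  int tfo_s, tfo_e, tts_s, tts_e;  // 1-based closed
  std::string strand, motif, orientation, errpos;
  int len, errors;
  double gfrac, gafrac;
};

}  // namespace

// [[Rcpp::export(name = ".triplexScanCpp")]]
DataFrame triplexScanCpp(std::string rna, std::string dna, int minLength,
                         double maxErrorRate, int maxConsecutive,
                         double minGuanine, CharacterVector motifs) {
  for (auto &c : rna) { c = toupper(c); if (c == 'U') c = 'T'; }
  for (auto &c : dna) c = toupper(c);
  const int m = (int)rna.size(), n = (int)dna.size();
  std::vector<Rec> out;
  std::set<std::tuple<int,int,int,int,std::string,std::string>> seen;
  if (m < minLength || n < minLength) return DataFrame::create();

  std::string rnaRev(rna.rbegin(), rna.rend());
  const char *motifName[3] = {"pyrimidine", "purine", "mixed"};

  // per-diagonal work buffers, allocated once
  const int Lmax = std::min(m, n);
  std::vector<int> mism(Lmax + 1), gcnt(Lmax + 1), gacnt(Lmax + 1);
  std::vector<int> nextRun(Lmax + 2);
  std::vector<char> isRun(Lmax);

  for (int mi = 0; mi < (int)motifs.size(); ++mi) {
    std::string mn = as<std::string>(motifs[mi]);
    int motif = mn == "pyrimidine" ? 0 : (mn == "purine" ? 1 : 2);
    std::vector<int> orients;  // 0 = parallel, 1 = antiparallel
    if (motif == 0) orients = {0};
    else if (motif == 1) orients = {1};
    else orients = {0, 1};

    for (int strand = 0; strand < 2; ++strand) {  // purine strand: 0='+',1='-'
      std::string pur = strand == 0 ? dna : revcomp(dna);
      for (int ori : orients) {
        const std::string &q = ori == 0 ? rna : rnaRev;
        // diagonal d: q[i] aligned with pur[i + d]
        for (int d = -(m - minLength); d <= n - minLength; ++d) {
          int i0 = std::max(0, -d);
          int i1 = std::min(m - 1, n - 1 - d);
          int L = i1 - i0 + 1;
          if (L < minLength) continue;
          // per-position prefix arrays over the diagonal overlap [0, L)
          mism[0] = gcnt[0] = gacnt[0] = 0;
          for (int t = 0; t < L; ++t) {
            char qc = q[i0 + t], pc = pur[i0 + t + d];
            mism[t + 1] = mism[t] + (hoogsteen(qc, pc, motif) ? 0 : 1);
            gcnt[t + 1] = gcnt[t] + (pc == 'G' ? 1 : 0);
            gacnt[t + 1] = gacnt[t] + (pc == 'G' || pc == 'A' ? 1 : 0);
          }
          // any valid window needs more than minLength*(1-rate) matches;
          // skip diagonals that cannot reach that
          if (L - mism[L] < minLength - (int)(maxErrorRate * minLength))
            continue;
          // nextRun[s] = smallest a >= s with (maxConsecutive+1) straight
          // errors starting at a (0-based), else BIG
          int runLen = maxConsecutive + 1;
          {
            int streak = 0;
            std::fill(isRun.begin(), isRun.begin() + L, 0);
            for (int t = 0; t < L; ++t) {
              streak = (mism[t + 1] - mism[t]) ? streak + 1 : 0;
              if (streak >= runLen) isRun[t - runLen + 1] = 1;
            }
            nextRun[L] = nextRun[L + 1] = BIG;
            for (int s = L - 1; s >= 0; --s)
              nextRun[s] = isRun[s] ? s : nextRun[s + 1];
          }
          auto valid = [&](int s, int e) {  // 0-based closed within diagonal
            if (s < 0 || e >= L) return false;
            int len = e - s + 1;
            if (len < minLength) return false;
            int err = mism[e + 1] - mism[s];
            if ((double)err / len >= maxErrorRate) return false;
            if (nextRun[s] + runLen - 1 <= e) return false;
            if ((double)(gcnt[e + 1] - gcnt[s]) / len < minGuanine) return false;
            return true;
          };
          for (int s = 0; s < L; ++s) {
            int eCap = std::min(L - 1, nextRun[s] + runLen - 2);
            for (int e = s + minLength - 1; e <= eCap; ++e) {
              if (!valid(s, e)) continue;
              if (valid(s - 1, e) || valid(s, e + 1)) continue;  // not maximal
              int len = e - s + 1;
              // coordinates (0-based) on q and purine strand
              int qs = i0 + s, qe = i0 + e;
              int ps = qs + d, pe = qe + d;
              // tfo on original rna (1-based closed)
              int tfo_s, tfo_e;
              if (ori == 0) { tfo_s = qs + 1; tfo_e = qe + 1; }
              else { tfo_s = m - qe; tfo_e = m - qs; }
              // tts on original dna (1-based closed)
              int tts_s, tts_e;
              if (strand == 0) { tts_s = ps + 1; tts_e = pe + 1; }
              else { tts_s = n - pe; tts_e = n - ps; }
              auto key = std::make_tuple(tfo_s, tfo_e, tts_s, tts_e,
                                         std::string(motifName[motif]),
                                         std::string(ori == 0 ? "parallel"
                                                              : "antiparallel"));
              if (!seen.insert(key).second) continue;
              Rec r;
              r.tfo_s = tfo_s; r.tfo_e = tfo_e;
              r.tts_s = tts_s; r.tts_e = tts_e;
              r.strand = strand == 0 ? "+" : "-";
              r.motif = motifName[motif];
              r.orientation = ori == 0 ? "parallel" : "antiparallel";
              r.len = len;
              r.errors = mism[e + 1] - mism[s];
              r.gfrac = (double)(gcnt[e + 1] - gcnt[s]) / len;
              r.gafrac = (double)(gacnt[e + 1] - gacnt[s]) / len;
              std::string ep;
              for (int t = s; t <= e; ++t)
                if (mism[t + 1] - mism[t]) {
                  if (!ep.empty()) ep += ",";
                  ep += std::to_string(t - s + 1);
                }
              r.errpos = ep;
              out.push_back(r);
            }
          }
        }
      }
    }
  }

  int N = (int)out.size();
  IntegerVector tfs(N), tfe(N), tts(N), tte(N), len(N), err(N);
  CharacterVector str(N), mot(N), ori(N), epos(N);
  NumericVector gf(N), gaf(N), score(N);
  for (int k = 0; k < N; ++k) {
    tfs[k] = out[k].tfo_s; tfe[k] = out[k].tfo_e;
    tts[k] = out[k].tts_s; tte[k] = out[k].tts_e;
    str[k] = out[k].strand; mot[k] = out[k].motif; ori[k] = out[k].orientation;
    len[k] = out[k].len; err[k] = out[k].errors;
    score[k] = out[k].len - out[k].errors;
    gf[k] = out[k].gfrac; gaf[k] = out[k].gafrac; epos[k] = out[k].errpos;
  }
  return DataFrame::create(
    _["tfo_start"] = tfs, _["tfo_end"] = tfe,
    _["tts_start"] = tts, _["tts_end"] = tte,
    _["tts_strand"] = str, _["motif"] = mot, _["orientation"] = ori,
    _["length"] = len, _["errors"] = err, _["score"] = score,
    _["guanine_fraction"] = gf, _["ga_fraction"] = gaf,
    _["error_positions"] = epos, _["stringsAsFactors"] = false);
}
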