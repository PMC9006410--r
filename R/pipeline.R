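#' Run the full lncRNA discovery and profiling pipeline
#'
#' Executes the stages in order on the files of an input directory (as
#' written by [writeStudy()]): \emph{classify} (class codes + candidate
#' filter), \emph{codepot} (coding-potential model trained on the
#' reference mRNA/lncRNA sets, cutoff calibration, ORF/homology discard),
#' \emph{de} (NB Wald differential expression and TPM), \emph{corr}
#' (per-group Spearman DEL:DEG network) and \emph{triplex} (TFO/TTS scan
#' of each negatively correlated mated DEL against its partner's locus).
#' Each stage writes its TSV outputs before the next starts, and a
#' machine-readable run report (JSON) records parameters, per-stage counts
#' and wall-clock times. Re-running with an identical input directory and
#' parameters reproduces byte-identical outputs.
#'
#' @param inputDir Directory with genome.fasta, reference.gtf, novel.gtf,
#'   counts.tsv, samples.tsv, lengths.tsv.
#' @param outDir Output directory (created).
#' @param minLength Candidate length filter in nt (default 200).
#' @param cutoff Coding-probability cutoff; \code{NULL} = calibrate on the
#'   reference training set.
#' @param maxOrfAa ORF discard bound in codons (default 100).
#' @param hits Optional precomputed homology table (data.frame with
#'   \code{transcript_id}).
#' @param lfcMin,fdrMax DE call thresholds (defaults 1, 0.01).
#' @param rhoMin,pMax Edge thresholds (defaults 0.8, 0.01).
#' @param triplexPar A [triplexParams()] object.
#' @param locusFlank Flank around partner gene spans scanned for TTSs
#'   (default 2000 bp).
#' @return Invisibly, a list with the run report and the main stage
#'   results (\code{candidates}, \code{scored}, \code{lncrnaIds},
#'   \code{de}, \code{edges}, \code{triplex}).
#' @export
runPipeline <- function(inputDir, outDir, minLength = 200, cutoff = NULL,
                        maxOrfAa = 100, hits = NULL, lfcMin = 1,
                        fdrMax = 0.01, rhoMin = 0.8, pMax = 0.01,
                        triplexPar = triplexParams(), locusFlank = 2000) {
  t0 <- proc.time()[["elapsed"]]
  need <- c("genome.fasta", "reference.gtf", "novel.gtf", "counts.tsv",
            "samples.tsv", "lengths.tsv")
  for (f in need) {
    if (!file.exists(file.path(inputDir, f)))
      stop("stage ", if (f == "counts.tsv") "de" else "classify",
           ": missing input file ", f)
  }
  dir.create(outDir, showWarnings = FALSE, recursive = TRUE)
  report <- list(parameters = list(
    minLength = minLength, cutoff = if (is.null(cutoff)) "auto" else cutoff,
    maxOrfAa = maxOrfAa, lfcMin = lfcMin, fdrMax = fdrMax,
    rhoMin = rhoMin, pMax = pMax,
    triplex = unclass(triplexPar), locusFlank = locusFlank),
    version = as.character(utils::packageVersion("lncScout")),
    stages = list())
  tick <- function() proc.time()[["elapsed"]]
  emit <- function(df, f) utils::write.table(
    df, file.path(outDir, f), sep = "\t", quote = FALSE, row.names = FALSE)

  ## stage 1: classify -----------------------------------------------------
  ts <- tick()
  genome <- readFasta(file.path(inputDir, "genome.fasta"))
  reference <- readGtf(file.path(inputDir, "reference.gtf"))
  novel <- readGtf(file.path(inputDir, "novel.gtf"))
  candidates <- filterCandidates(novel, reference, minLength = minLength)
  emit(candidates, "candidates.tsv")
  report$stages$classify <- list(
    input = nrow(candidates), kept = sum(candidates$verdict == "kept"),
    rejected = sum(candidates$verdict == "rejected"),
    seconds = round(tick() - ts, 3))

  ## stage 2: coding potential --------------------------------------------
  ts <- tick()
  refSeqs <- extractTxSeqs(reference, genome)
  novSeqs <- extractTxSeqs(novel, genome)
  bt <- txBiotype(reference)
  codingIds <- names(bt)[bt == "mRNA"]
  noncodingIds <- names(bt)[bt == "lncRNA"]
  if (length(codingIds) < 10 || length(noncodingIds) < 10)
    stop("stage codepot: reference training sets too small")
  orfSeqs <- vapply(codingIds, function(id) {
    o <- longestOrf(refSeqs[[id]])
    if (is.null(o)) "" else substr(as.character(refSeqs[[id]]), o$start, o$end)
  }, "")
  hex <- buildHexamerTable(orfSeqs[nzchar(orfSeqs)],
                           as.character(refSeqs[noncodingIds]))
  trainFeat <- codingFeatures(refSeqs[c(codingIds, noncodingIds)], hex)
  labels <- c(rep(TRUE, length(codingIds)), rep(FALSE, length(noncodingIds)))
  model <- trainCodingModel(trainFeat, labels, hex)
  useCutoff <- if (is.null(cutoff)) model@cutoff else cutoff
  candIds <- candidates$transcript_id[candidates$verdict == "kept"]
  scored <- if (length(candIds)) {
    feat <- codingFeatures(novSeqs[candIds], hex)
    data.frame(transcript_id = candIds, feat,
               coding_prob = codingProbability(model, feat),
               row.names = NULL, stringsAsFactors = FALSE)
  } else data.frame(transcript_id = character(0), coding_prob = numeric(0))
  emit(scored, "coding_scores.tsv")
  belowCut <- scored$transcript_id[scored$coding_prob < useCutoff]
  orfFilt <- orfHomologyFilter(belowCut, novSeqs, maxOrfAa = maxOrfAa,
                               hits = hits)
  emit(orfFilt, "orf_filter.tsv")
  lncrnaIds <- orfFilt$transcript_id[orfFilt$verdict == "kept"]
  emit(data.frame(transcript_id = lncrnaIds), "novel_lncrna.tsv")
  report$stages$codepot <- list(
    input = length(candIds), cutoff = useCutoff,
    model_accuracy = model@accuracy, model_auc = model@auc,
    below_cutoff = length(belowCut), kept = length(lncrnaIds),
    rejected = length(candIds) - length(lncrnaIds),
    seconds = round(tick() - ts, 3))

  ## stage 3: differential expression -------------------------------------
  ts <- tick()
  counts <- readCountsTsv(file.path(inputDir, "counts.tsv"))
  sheet <- readSampleSheet(file.path(inputDir, "samples.tsv"))
  lengths <- utils::read.delim(file.path(inputDir, "lengths.tsv"))
  lens <- stats::setNames(lengths$length, lengths$feature_id)
  se <- makeCountExperiment(counts, sheet, lens)
  de <- runDEAnalysis(se, lfcMin = lfcMin, fdrMax = fdrMax)
  emit(data.frame(feature_id = rownames(de), de, row.names = NULL),
       "de_results.tsv")
  tpm <- computeTpm(counts, lens[rownames(counts)])
  lncFeatures <- union(noncodingIds, lncrnaIds)
  dels <- rownames(de)[de$flag != "ns" & rownames(de) %in% lncFeatures]
  degs <- rownames(de)[de$flag != "ns" & rownames(de) %in% codingIds]
  report$stages$de <- list(
    input = nrow(counts), tested = sum(de$kept),
    filtered = sum(!de$kept),
    deg_up_in_mated = sum(de$flag == "up_in_mated" & rownames(de) %in% codingIds),
    deg_up_in_virgin = sum(de$flag == "up_in_virgin" & rownames(de) %in% codingIds),
    dels = length(dels), degs = length(degs),
    seconds = round(tick() - ts, 3))

  ## stage 4: correlation network ------------------------------------------
  ts <- tick()
  edges <- if (length(dels) && length(degs))
    buildNetwork(tpm, dels, degs, sheet, rhoMin = rhoMin, pMax = pMax)
  else .emptyEdges()
  emit(edges, "edges.tsv")
  flags <- stats::setNames(de$flag, rownames(de))
  cats <- pairCategories(edges, flags)
  emit(cats, "pair_categories.tsv")
  report$stages$corr <- list(
    pairs_tested = length(dels) * length(degs) * 2L,
    edges = nrow(edges),
    edges_virgin = sum(edges$group == "virgin"),
    edges_mated = sum(edges$group == "mated"),
    seconds = round(tick() - ts, 3))

  ## stage 5: triplex scan --------------------------------------------------
  ## for every mated DEL, scan the loci of its negatively correlated DEG
  ## partners: retained negative edges plus the top-3 most anti-correlated
  ## DEGs (a candidate-target shortlist independent of the edge p cutoff)
  ts <- tick()
  triRows <- list()
  neg <- edges[edges$group == "mated" & edges$sign == "negative",
               c("lncrna_id", "mrna_id"), drop = FALSE]
  if (length(dels) && length(degs)) {
    matedCols <- sheet$sample_id[sheet$group == "mated"]
    for (lid in dels) {
      rr <- vapply(degs, function(mid)
        suppressWarnings(stats::cor(tpm[lid, matedCols], tpm[mid, matedCols],
                                    method = "spearman")), 0)
      top <- names(sort(rr[rr < 0]))[seq_len(min(3, sum(rr < 0, na.rm = TRUE)))]
      if (length(top))
        neg <- rbind(neg, data.frame(lncrna_id = lid, mrna_id = top))
    }
    neg <- unique(neg)
    neg <- neg[order(neg$lncrna_id, neg$mrna_id), , drop = FALSE]
  }
  allSeqs <- c(refSeqs, novSeqs)
  gid <- geneIds(reference)
  if (nrow(neg)) {
    for (k in seq_len(nrow(neg))) {
      lid <- neg$lncrna_id[k]; mid <- neg$mrna_id[k]
      if (!mid %in% txIds(reference) || !lid %in% names(allSeqs)) next
      sp <- txSpan(reference[mid])
      scf <- as.character(GenomicRanges::seqnames(sp))
      locus <- GRanges(scf, IRanges(
        max(1L, GenomicRanges::start(sp) - locusFlank),
        min(length(genome[[scf]]),
            GenomicRanges::end(sp) + locusFlank)))
      m <- scanLncrnaVsLocus(allSeqs[[lid]], genome, locus, reference,
                             unname(gid[mid]), params = triplexPar)
      if (nrow(m))
        triRows[[length(triRows) + 1L]] <-
          data.frame(lncrna_id = lid, target_mrna = mid, m,
                     stringsAsFactors = FALSE)
    }
  }
  triplex <- if (length(triRows)) do.call(rbind, triRows) else
    data.frame(lncrna_id = character(0), target_mrna = character(0),
               .emptyTriplexDf(), scaffold = character(0),
               tts_genomic_start = integer(0), tts_genomic_end = integer(0),
               feature = character(0))
  emit(triplex, "triplex.tsv")
  report$stages$triplex <- list(
    loci_scanned = nrow(neg), matches = nrow(triplex),
    seconds = round(tick() - ts, 3))

  report$total_seconds <- round(tick() - t0, 3)
  jsonlite::write_json(report, file.path(outDir, "report.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(list(report = report, candidates = candidates, scored = scored,
                 lncrnaIds = lncrnaIds, de = de, tpm = tpm, edges = edges,
                 categories = cats, triplex = triplex, model = model))
}

.emptyEdges <- function() {
  data.frame(lncrna_id = character(0), mrna_id = character(0),
             group = character(0), rho = numeric(0), p = numeric(0),
             sign = character(0))
}

#' Score pipeline outputs against simulation ground truth
#'
#' Computes per-stage sensitivity and precision from the truth tables of
#' [simulateStudy()]: novel-lncRNA identification (planted i/y/p/u
#' transcripts vs identified set), DE calls (planted nonzero log2FC among
#' tested features), planted correlated pairs recovered as mated edges,
#' and recovery of the planted triplex tract (any reported TTS
#' overlapping it).
#'
#' @param result Return value of [runPipeline()].
#' @param truth The \code{truth} element of [simulateStudy()].
#' @return data.frame with \code{stage}, \code{metric}, \code{value}
#'   (NA where undefined, e.g. precision with no calls).
#' @export
evaluateAgainstTruth <- function(result, truth) {
  rate <- function(num, den) if (den == 0) NA_real_ else num / den
  trueLnc <- truth$novel$transcript_id[truth$novel$true_class %in%
                                         c("i", "y", "p", "u")]
  predLnc <- result$lncrnaIds
  if (length(setdiff(predLnc, truth$novel$transcript_id)))
    stop("identified ids absent from truth table")
  m <- list(
    c("lncrna", "sensitivity", rate(length(intersect(predLnc, trueLnc)),
                                    length(trueLnc))),
    c("lncrna", "precision", rate(length(intersect(predLnc, trueLnc)),
                                  length(predLnc))))
  de <- result$de
  tested <- rownames(de)[de$kept]
  tt <- truth$expression
  trueDe <- tt$feature_id[tt$de & tt$feature_id %in% tested]
  predDe <- rownames(de)[de$flag != "ns"]
  m <- c(m, list(
    c("de", "sensitivity", rate(length(intersect(predDe, trueDe)),
                                length(trueDe))),
    c("de", "precision", rate(length(intersect(predDe, trueDe)),
                              length(predDe)))))
  if (!is.null(truth$pairs) && nrow(truth$pairs)) {
    key <- paste(truth$pairs$a, truth$pairs$b)
    ek <- paste(result$edges$lncrna_id, result$edges$mrna_id)[
      result$edges$group == "mated"]
    m <- c(m, list(c("corr", "pair_recall", rate(sum(key %in% ek), length(key)))))
  }
  if (!is.null(truth$triplex)) {
    tr <- truth$triplex
    hit <- nrow(result$triplex) > 0 &&
      any(result$triplex$scaffold == tr$scaffold &
            result$triplex$tts_genomic_start <= tr$tract_end &
            result$triplex$tts_genomic_end >= tr$tract_start)
    m <- c(m, list(c("triplex", "plant_recovered", as.numeric(hit))))
  }
  out <- as.data.frame(do.call(rbind, m), stringsAsFactors = FALSE)
  colnames(out) <- c("stage", "metric", "value")
  out$value <- as.numeric(out$value)
  out
}
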