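#' Configuration for the synthetic two-state brain RNA-seq study
#'
#' Defaults emulate the downstream products of a two-state (virgin alate
#' vs mated dealate) queen-brain study: a reference annotation with
#' multi-exon mRNAs and spliced (>= 2 exon) lncRNAs, planted single-exon
#' novel transcripts of class codes i/y/p/u plus exon-overlapping decoys,
#' negative-binomial counts for 2 groups x 4 biological replicates x 4
#' technical runs (32 libraries), planted two-fold-and-larger expression
#' changes, high-|rho| lncRNA:mRNA pairs via a Gaussian copula, and one
#' GA-rich triplex target tract inside a first intron.
#'
#' @param seed Integer master seed; every generator derives its stream
#'   from it.
#' @param nScaffolds,scaffoldLength Genome shape (default 4 x 150 kb).
#' @param nRefMrna,nRefLncrna Reference gene counts (default 40 + 20).
#' @param nNovel Named integer vector, plants per class code
#'   (default i=12, y=8, p=12, u=16).
#' @param nDecoy Exon-overlapping decoy transcripts (default 10).
#' @param novelLengthRange Novel exon length range in nt.
#' @param orfMinCodons Minimum ORF length of reference mRNAs, in codons
#'   (default 120, i.e. >= 360 nt).
#' @param codonBias Strength of the first-order codon bias of coding
#'   sequence (log-scale sd of codon weights; 0 = uniform).
#' @param nBioReps,nTechRuns Biological replicates per group and technical
#'   runs per replicate (default 4 x 4).
#' @param meanRange Log-uniform range of NB base means.
#' @param dispersionRange Uniform range of NB dispersions.
#' @param libFactorRange Uniform range of per-library size factors.
#' @param plantedLog2FC Magnitude of planted fold changes (default 2).
#' @param nDeMrna,nDeLnc Planted DE feature counts (half up, half down).
#' @param nPairs,targetRho Planted correlated DEL:DEG pairs and the copula
#'   correlation (default 6 pairs at 0.95, planted in the mated group).
#' @param tractLength,tractPurity Triplex plant: GA tract length (40 nt)
#'   and purine purity (1.0).
#' @return A validated list of class \code{"SimulationConfig"}.
#' @export
simulationConfig <- function(seed = 1L, nScaffolds = 4, scaffoldLength = 400000,
                             nRefMrna = 40, nRefLncrna = 20,
                             nNovel = c(i = 12, y = 8, p = 12, u = 16),
                             nDecoy = 10, novelLengthRange = c(250, 600),
                             orfMinCodons = 120, codonBias = 1,
                             nBioReps = 4, nTechRuns = 4,
                             meanRange = c(20, 2000),
                             dispersionRange = c(0.05, 0.3),
                             libFactorRange = c(0.7, 1.4),
                             plantedLog2FC = 2, nDeMrna = 12, nDeLnc = 8,
                             nPairs = 6, targetRho = 0.95,
                             tractLength = 40, tractPurity = 1.0) {
  stopifnot(nScaffolds >= 1, scaffoldLength > 10000,
            all(nNovel >= 0), nDecoy >= 0, all(dispersionRange > 0),
            abs(targetRho) <= 1, tractPurity >= 0, tractPurity <= 1,
            nBioReps >= 2, nTechRuns >= 1, all(meanRange > 0))
  if (!all(c("i", "y", "p", "u") %in% names(nNovel)))
    stop("nNovel must name classes i, y, p, u")
  structure(as.list(environment()), class = "SimulationConfig")
}

.randomDna <- function(n, probs = rep(0.25, 4)) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE, prob = probs),
        collapse = "")
}

## noncoding sequence free of complete ORFs of >= maxCodons codons
.noncodingSeq <- function(len, maxCodons = 100) {
  for (try in 1:100) {
    s <- .randomDna(len)
    orfs <- findOrfs(s)
    orfs <- orfs[orfs$has_stop, , drop = FALSE]
    if (!nrow(orfs) || max(orfs$length_nt) / 3 - 1 < maxCodons) return(s)
  }
  stop("could not generate ORF-free noncoding sequence of length ", len)
}

.senseCodons <- local({
  b <- c("A", "C", "G", "T")
  all <- apply(expand.grid(b, b, b), 1, paste, collapse = "")
  setdiff(all, c("TAA", "TAG", "TGA"))
})

## codon-biased coding sequence: UTR5 + ATG + biased codons + stop + UTR3
.codingSeq <- function(nCodons, codonWeights, utr5, utr3) {
  body <- paste(sample(.senseCodons, nCodons - 2L, replace = TRUE,
                       prob = codonWeights), collapse = "")
  paste0(.randomDna(utr5), "ATG", body, sample(c("TAA", "TAG", "TGA"), 1),
         .randomDna(utr3))
}

## overwrite genome exon regions with a spliced transcript sequence
.writeTxSeq <- function(genome, exons, splicedSeq) {
  scf <- as.character(GenomicRanges::seqnames(exons))[1]
  neg <- as.character(GenomicRanges::strand(exons))[1] == "-"
  s <- if (neg) as.character(
    Biostrings::reverseComplement(Biostrings::DNAString(splicedSeq)))
  else splicedSeq
  pos <- 1L
  for (k in seq_along(exons)) {
    w <- GenomicRanges::width(exons)[k]
    piece <- substr(s, pos, pos + w - 1L)
    Biostrings::subseq(genome[[scf]], GenomicRanges::start(exons)[k],
                       GenomicRanges::end(exons)[k]) <- Biostrings::DNAString(piece)
    pos <- pos + w
  }
  genome
}

#' Simulate a genome with a reference annotation
#'
#' Places reference mRNA and lncRNA genes along random scaffolds with wide
#' intergenic gaps (>= 6 kb). mRNAs get 3-6 exons with a codon-biased ORF
#' of at least \code{orfMinCodons} codons; reference lncRNAs get 2-3
#' exons of ORF-free, compositionally uniform sequence (so a coding
#' potential model is learnable from the composition gap). The first
#' few lncRNA genes are compact (small genomic span) so class-y novels
#' can later wrap them inside an intron.
#'
#' @param config A [simulationConfig()].
#' @return List with \code{genome} (\code{DNAStringSet}),
#'   \code{reference} ([TranscriptSet-class]) and \code{truth}
#'   (per-transcript data.frame).
#' @export
simulateGenomeAnnotation <- function(config) {
  stopifnot(inherits(config, "SimulationConfig"))
  set.seed(config$seed)
  nS <- config$nScaffolds
  scf <- sprintf("scaffold_%02d", seq_len(nS))
  genome <- Biostrings::DNAStringSet(vapply(
    seq_len(nS), function(i) .randomDna(config$scaffoldLength), ""))
  names(genome) <- scf

  codonWeights <- exp(config$codonBias * stats::rnorm(length(.senseCodons)))

  nM <- config$nRefMrna; nL <- config$nRefLncrna
  specs <- data.frame(
    kind = c(rep("mRNA", nM), rep("lncRNA", nL)),
    id = c(sprintf("tM%03d", seq_len(nM)), sprintf("tL%03d", seq_len(nL))),
    gene = c(sprintf("gM%03d", seq_len(nM)), sprintf("gL%03d", seq_len(nL))),
    compact = c(rep(FALSE, nM), seq_len(nL) <= config$nNovel[["y"]]),
    stringsAsFactors = FALSE)
  specs <- specs[sample.int(nrow(specs)), , drop = FALSE]
  specs$scaffold <- rep_len(scf, nrow(specs))

  exonsList <- list(); meta <- list()
  cursor <- stats::setNames(rep(3000L, nS), scf)
  for (r in seq_len(nrow(specs))) {
    sp <- specs[r, ]
    strand <- sample(c("+", "-"), 1)
    if (sp$kind == "mRNA") {
      nex <- sample(3:6, 1)
      exLen <- sample(120:300, nex, replace = TRUE)
      inLen <- sample(300:1500, nex - 1, replace = TRUE)
      ## first intron (transcript order) wide enough to host plants
      if (strand == "+") inLen[1] <- max(inLen[1], 800L)
      else inLen[nex - 1] <- max(inLen[nex - 1], 800L)
    } else if (sp$compact) {
      nex <- 2L
      exLen <- sample(110:150, nex, replace = TRUE)
      inLen <- sample(120:200, nex - 1, replace = TRUE)
    } else {
      nex <- sample(2:3, 1)
      exLen <- sample(150:400, nex, replace = TRUE)
      inLen <- sample(300:1200, nex - 1, replace = TRUE)
    }
    gap <- sample(6000:12000, 1)
    start <- cursor[sp$scaffold] + gap
    starts <- start + cumsum(c(0L, exLen[-nex] + inLen))
    ends <- starts + exLen - 1L
    if (ends[nex] > config$scaffoldLength - 3000)
      stop("scaffold too short to place requested features")
    cursor[sp$scaffold] <- ends[nex]
    ex <- GRanges(sp$scaffold, IRanges(starts, ends), strand = strand)
    totalLen <- sum(exLen)
    seqStr <- if (sp$kind == "mRNA") {
      nCod <- max(config$orfMinCodons,
                  (totalLen - sample(30:120, 1) - sample(60:250, 1)) %/% 3 - 10)
      nCod <- min(nCod, (totalLen - 6) %/% 3)
      cds <- 3L * nCod
      utr5 <- sample(0:(totalLen - cds), 1)
      .codingSeq(nCod, codonWeights, utr5, totalLen - cds - utr5)
    } else .noncodingSeq(totalLen)
    genome <- .writeTxSeq(genome, ex, seqStr)
    exonsList[[sp$id]] <- ex
    meta[[sp$id]] <- data.frame(transcript_id = sp$id, gene_id = sp$gene,
                                biotype = sp$kind, compact = sp$compact,
                                stringsAsFactors = FALSE)
  }
  if (length(exonsList)) {
    ref <- TranscriptSet(methods::as(GRangesList(exonsList), "GRangesList"),
                         geneId = vapply(meta, function(m) m$gene_id, ""),
                         biotype = vapply(meta, function(m) m$biotype, ""))
  } else {
    ref <- TranscriptSet(GRangesList())
  }
  truth <- do.call(rbind, meta)
  if (is.null(truth))
    truth <- data.frame(transcript_id = character(0), gene_id = character(0),
                        biotype = character(0), compact = logical(0))
  rownames(truth) <- NULL
  list(genome = genome, reference = ref, truth = truth)
}

## first +-strand mRNA whose first intron can host the triplex tract
.triplexHostGene <- function(reference, tractLength) {
  ids <- txIds(reference)
  bt <- txBiotype(reference)
  for (id in ids[bt == "mRNA"]) {
    ex <- txExons(reference)[[id]]
    if (as.character(GenomicRanges::strand(ex))[1] != "+") next
    if (length(ex) < 2) next
    iw <- GenomicRanges::start(ex)[2] - GenomicRanges::end(ex)[1] - 1L
    if (iw >= tractLength + 40) return(id)
  }
  NA_character_
}

#' Plant novel transcripts of known class codes
#'
#' Plants one cohort per class code: class-i single-exon transcripts
#' strictly inside a reference mRNA intron; class-y two-exon transcripts
#' whose intron wraps a full compact reference transcript; class-p
#' single-exon transcripts 50-1500 bp downstream (strand-aware) of a
#' reference end without overlap; class-u single-exon transcripts at
#' least 2.5 kb from any reference; plus exon-overlapping single-exon
#' decoys. Planted i/y/p/u transcripts receive ORF-free noncoding
#' sequence written into the genome; decoys keep the underlying (partly
#' coding) genomic sequence.
#'
#' @param ref Output of [simulateGenomeAnnotation()] (list with
#'   \code{genome}, \code{reference}).
#' @param config A [simulationConfig()].
#' @return List with \code{novel} ([TranscriptSet-class]), updated
#'   \code{genome}, and \code{truth} (data.frame with
#'   \code{true_class}).
#' @export
simulateNovelTranscripts <- function(ref, config) {
  stopifnot(inherits(config, "SimulationConfig"))
  set.seed(config$seed + 1000L)
  reference <- ref$reference
  genome <- ref$genome
  if (length(reference) == 0 && sum(config$nNovel) + config$nDecoy > 0)
    stop("cannot plant novel transcripts against an empty annotation")
  ex <- txExons(reference)
  bt <- txBiotype(reference)
  spans <- if (length(reference)) txSpan(reference) else GRanges()
  occupied <- spans
  host <- .triplexHostGene(reference, config$tractLength)
  lenRange <- config$novelLengthRange

  out <- list(); truth <- list(); nid <- 0L
  addNovel <- function(exonsGr, cls, hostId, writeSeq = TRUE) {
    nid <<- nid + 1L
    id <- sprintf("MSTRG.%d", nid)
    if (writeSeq) {
      tot <- sum(GenomicRanges::width(exonsGr))
      genome <<- .writeTxSeq(genome, exonsGr, .noncodingSeq(tot))
    }
    out[[id]] <<- exonsGr
    occupied <<- c(occupied, range(exonsGr))
    truth[[id]] <<- data.frame(transcript_id = id, true_class = cls,
                               host = if (is.null(hostId)) NA_character_ else hostId,
                               stringsAsFactors = FALSE)
    id
  }
  rndLen <- function() sample(lenRange[1]:lenRange[2], 1)

  ## class i: inside a reference mRNA intron (triplex host excluded)
  iHosts <- txIds(reference)[bt == "mRNA" & lengths(ex) > 1]
  iHosts <- setdiff(iHosts, host)
  for (k in seq_len(config$nNovel[["i"]])) {
    placed <- FALSE
    for (try in 1:200) {
      h <- sample(iHosts, 1)
      e <- ex[[h]]
      iw <- GenomicRanges::start(e)[-1] - GenomicRanges::end(e)[-length(e)] - 1L
      len <- rndLen()
      ok <- which(iw >= len + 20L)
      if (!length(ok)) next
      j <- if (length(ok) == 1) ok else sample(ok, 1)
      is0 <- GenomicRanges::end(e)[j] + 1L
      s <- is0 + sample.int(iw[j] - len - 18L, 1) + 8L
      gr <- GRanges(GenomicRanges::seqnames(e)[1], IRanges(s, s + len - 1L),
                    strand = sample(c("+", "-"), 1))
      if (GenomicRanges::countOverlaps(gr, occupied, ignore.strand = TRUE) > 1) next
      addNovel(gr, "i", h); placed <- TRUE; break
    }
    if (!placed) stop("no intron long enough for class-i plant")
  }

  ## class y: two exons wrapping a compact reference transcript
  yHosts <- txIds(reference)[ref$truth$compact[match(txIds(reference),
                                                     ref$truth$transcript_id)]]
  if (config$nNovel[["y"]] > length(yHosts))
    stop("not enough compact reference genes for class-y plants")
  for (h in utils::head(yHosts, config$nNovel[["y"]])) {
    sp <- txSpan(reference[h])
    scfh <- as.character(GenomicRanges::seqnames(sp))
    e1 <- IRanges(GenomicRanges::start(sp) - 250L, GenomicRanges::start(sp) - 51L)
    e2 <- IRanges(GenomicRanges::end(sp) + 51L, GenomicRanges::end(sp) + 250L)
    gr <- GRanges(scfh, c(e1, e2), strand = sample(c("+", "-"), 1))
    addNovel(gr, "y", h)
  }

  ## class p: strand-aware downstream of a reference end, no overlap
  pHosts <- txIds(reference)[!ref$truth$compact[match(txIds(reference),
                                                      ref$truth$transcript_id)]]
  for (k in seq_len(config$nNovel[["p"]])) {
    placed <- FALSE
    for (try in 1:200) {
      h <- sample(pHosts, 1)
      sp <- txSpan(reference[h])
      strand <- as.character(GenomicRanges::strand(sp))
      len <- rndLen()
      d <- sample(50:1500, 1)
      if (d + len > 1999L) d <- 1999L - len
      if (strand == "+") {
        s <- GenomicRanges::end(sp) + d
        gr <- GRanges(as.character(GenomicRanges::seqnames(sp)),
                      IRanges(s, s + len - 1L), strand = "+")
      } else {
        e <- GenomicRanges::start(sp) - d
        gr <- GRanges(as.character(GenomicRanges::seqnames(sp)),
                      IRanges(e - len + 1L, e), strand = "-")
      }
      if (GenomicRanges::start(gr) < 100) next
      if (GenomicRanges::countOverlaps(gr, occupied, ignore.strand = TRUE) > 0) next
      ## keep clear of other references' runon windows and introns
      near <- GenomicRanges::distance(gr, spans, ignore.strand = TRUE)
      close <- which(!is.na(near) & near < 2000)
      if (!all(txIds(reference)[close] == h)) next
      addNovel(gr, "p", h); placed <- TRUE; break
    }
    if (!placed) stop("failed to place class-p plant")
  }

  ## class u: >= 2.5 kb from every reference (and clear of other plants)
  scfAll <- names(genome)
  for (k in seq_len(config$nNovel[["u"]])) {
    placed <- FALSE
    for (try in 1:500) {
      sc <- sample(scfAll, 1)
      len <- rndLen()
      s <- sample(3000:(config$scaffoldLength - len - 3000), 1)
      gr <- GRanges(sc, IRanges(s, s + len - 1L), strand = sample(c("+", "-"), 1))
      if (length(spans)) {
        d <- GenomicRanges::distance(gr, spans, ignore.strand = TRUE)
        if (any(!is.na(d) & d < 2500)) next
      }
      if (GenomicRanges::countOverlaps(gr, occupied, ignore.strand = TRUE) > 0) next
      addNovel(gr, "u", NULL); placed <- TRUE; break
    }
    if (!placed) stop("failed to place class-u plant")
  }

  ## decoys: single exon overlapping a reference exon (class o downstream)
  dHosts <- txIds(reference)[bt == "mRNA"]
  for (k in seq_len(config$nDecoy)) {
    h <- sample(dHosts, 1)
    e <- ex[[h]]
    j <- sample(seq_along(e), 1)
    s <- GenomicRanges::start(e)[j] - sample(20:60, 1)
    en <- GenomicRanges::start(e)[j] +
      min(sample(150:400, 1), GenomicRanges::width(e)[j] - 1L)
    gr <- GRanges(GenomicRanges::seqnames(e)[1], IRanges(s, en),
                  strand = as.character(GenomicRanges::strand(e))[1])
    addNovel(gr, "decoy", h, writeSeq = FALSE)
  }

  novel <- if (length(out))
    TranscriptSet(methods::as(GRangesList(out), "GRangesList"),
                  biotype = "novel")
  else TranscriptSet(GRangesList())
  tdf <- if (length(truth)) do.call(rbind, truth) else
    data.frame(transcript_id = character(0), true_class = character(0),
               host = character(0))
  rownames(tdf) <- NULL
  list(novel = novel, genome = genome, truth = tdf)
}

#' Simulate NB counts for the two-state replicate design
#'
#' Counts follow a Gamma-Poisson (negative binomial) hierarchy: each
#' biological replicate draws a latent gene expression
#' \code{lambda ~ Gamma(1/alpha, scale = alpha * mu)} (so the marginal is
#' NB with mean \code{mu} and dispersion \code{alpha}); its technical
#' runs are independent Poisson resamples of \code{s * lambda} with a
#' per-library size factor \code{s}. Mated-group means are scaled by
#' \code{2^log2FC}. Planted correlated pairs draw their latent expression
#' from a shared Gaussian copula per library (NB marginals preserved), so
#' the planted rank correlation is expressed across all libraries of the
#' group rather than only across biological replicates. Dispersions below
#' 1e-4 collapse to the Poisson limit (\code{lambda = mu}).
#'
#' @param means Named numeric of NB base means (virgin scale).
#' @param log2FC Numeric of planted log2 fold changes (mated vs virgin),
#'   same length/order as \code{means}.
#' @param dispersions NB dispersions, recycled over genes.
#' @param config A [simulationConfig()] (replicate design, library factor
#'   range).
#' @param pairs Optional data.frame of planted pairs with columns
#'   \code{a}, \code{b} (feature ids), \code{rho}, \code{group}
#'   (\code{"virgin"}, \code{"mated"} or \code{"both"}).
#' @param seed Seed for this generator (default derived from the config).
#' @return List with \code{counts} (integer matrix, features x 2 *
#'   nBioReps * nTechRuns libraries) and \code{sampleSheet}.
#' @export
simulateCounts <- function(means, log2FC, dispersions, config,
                           pairs = NULL, seed = config$seed + 2000L) {
  stopifnot(inherits(config, "SimulationConfig"),
            length(log2FC) == length(means))
  if (any(means <= 0)) stop("NB means must be positive")
  set.seed(seed)
  G <- length(means)
  ids <- names(means)
  alpha <- rep_len(dispersions, G)
  nB <- config$nBioReps; nT <- config$nTechRuns
  groups <- c("virgin", "mated")
  counts <- NULL; sheet <- list()
  qlam <- function(z, i) {
    if (alpha[i] < 1e-4) return(rep(muNow[i], length(z)))
    stats::qgamma(stats::pnorm(z), shape = 1 / alpha[i],
                  scale = alpha[i] * muNow[i])
  }
  for (g in groups) {
    mu <- means * if (g == "mated") 2^log2FC else 1
    muNow <- mu
    activePairs <- if (is.null(pairs)) NULL else
      pairs[pairs$group %in% c(g, "both"), , drop = FALSE]
    for (j in seq_len(nB)) {
      z <- stats::rnorm(G)
      pois <- alpha < 1e-4
      lam <- numeric(G)
      lam[pois] <- mu[pois]
      if (any(!pois))
        lam[!pois] <- stats::qgamma(stats::pnorm(z[!pois]),
                                    shape = 1 / alpha[!pois],
                                    scale = alpha[!pois] * mu[!pois])
      for (r in seq_len(nT)) {
        s <- stats::runif(1, config$libFactorRange[1], config$libFactorRange[2])
        cnt <- stats::rpois(G, s * lam)
        ## planted pairs: correlated latent drawn per library, so the
        ## rank correlation is expressed across all n = 16 samples
        if (!is.null(activePairs) && nrow(activePairs)) {
          for (q in seq_len(nrow(activePairs))) {
            ia <- match(activePairs$a[q], ids)
            ib <- match(activePairs$b[q], ids)
            ## the target is the Spearman correlation of the counts, so the
            ## copula Pearson correlation compensates the rank/linear map
            ## (2 sin(pi rho / 6)) and, to first order, the Poisson
            ## counting noise (variance 1/(alpha mu) relative to the
            ## latent Gamma variance); capped below 1
            att <- sqrt((1 + 1 / (max(alpha[ia], 1e-4) * muNow[ia])) *
                          (1 + 1 / (max(alpha[ib], 1e-4) * muNow[ib])))
            rhoCop <- sign(activePairs$rho[q]) *
              min(0.999, 2 * sin(pi * abs(activePairs$rho[q]) / 6) * att)
            za <- stats::rnorm(1)
            zb <- rhoCop * za + sqrt(1 - rhoCop^2) * stats::rnorm(1)
            cnt[ia] <- stats::rpois(1, s * qlam(za, ia))
            cnt[ib] <- stats::rpois(1, s * qlam(zb, ib))
          }
        }
        counts <- cbind(counts, cnt)
        sheet[[length(sheet) + 1L]] <- data.frame(
          sample_id = sprintf("%s_b%d_t%d", g, j, r), group = g,
          biological_replicate = j, technical_run = r,
          stringsAsFactors = FALSE)
      }
    }
  }
  sheet <- do.call(rbind, sheet)
  dimnames(counts) <- list(ids, sheet$sample_id)
  storage.mode(counts) <- "integer"
  list(counts = counts, sampleSheet = sheet)
}

#' Plant a triplex target tract and its TFO
#'
#' Writes a GA-rich purine tract (length and purity from the config) into
#' the first intron of the designated host mRNA (a plus-strand gene) and
#' the pyrimidine-motif parallel TFO complement (G -> C, A -> U; impure
#' tract bases get a guaranteed-mismatching G) into the middle of the
#' chosen lncRNA's exonic sequence.
#'
#' @param genome \code{DNAStringSet} to modify.
#' @param reference Reference [TranscriptSet-class].
#' @param novel Novel [TranscriptSet-class] containing \code{lncrnaId}.
#' @param lncrnaId The transcript carrying the TFO.
#' @param config A [simulationConfig()].
#' @return List with updated \code{genome} and \code{truth} (host gene,
#'   tract scaffold/coordinates, TFO transcript coordinates).
#' @export
plantTriplex <- function(genome, reference, novel, lncrnaId, config) {
  stopifnot(inherits(config, "SimulationConfig"))
  set.seed(config$seed + 3000L)
  host <- .triplexHostGene(reference, config$tractLength)
  if (is.na(host)) stop("no reference intron available for the triplex plant")
  ex <- txExons(reference)[[host]]
  L <- config$tractLength
  intronStart <- GenomicRanges::end(ex)[1] + 1L
  intronEnd <- GenomicRanges::start(ex)[2] - 1L
  s <- intronStart + ((intronEnd - intronStart + 1L - L) %/% 2L)
  pure <- stats::runif(L) < config$tractPurity
  tract <- ifelse(pure, sample(c("G", "A"), L, replace = TRUE),
                  sample(c("C", "T"), L, replace = TRUE))
  scf <- as.character(GenomicRanges::seqnames(ex))[1]
  Biostrings::subseq(genome[[scf]], s, s + L - 1L) <-
    Biostrings::DNAString(paste(tract, collapse = ""))
  ## pyrimidine parallel TFO: G.C, A.T(U); impure positions mismatch
  tfo <- ifelse(tract == "G", "C", ifelse(tract == "A", "T", "G"))
  nex <- txExons(novel)[[lncrnaId]]
  neg <- as.character(GenomicRanges::strand(nex))[1] == "-"
  tlen <- sum(GenomicRanges::width(nex))
  if (tlen < L + 2) stop("lncRNA too short to carry the TFO")
  tfoStart <- (tlen - L) %/% 2L + 1L
  seqs <- extractTxSeqs(novel[lncrnaId], genome)
  txt <- as.character(seqs[[1]])
  substr(txt, tfoStart, tfoStart + L - 1L) <- paste(tfo, collapse = "")
  genome <- .writeTxSeq(genome, nex, txt)
  list(genome = genome,
       truth = data.frame(host_transcript = host,
                          lncrna_id = lncrnaId,
                          scaffold = scf, tract_start = s,
                          tract_end = s + L - 1L,
                          tfo_start = tfoStart, tfo_end = tfoStart + L - 1L,
                          stringsAsFactors = FALSE))
}

#' Simulate the complete synthetic study
#'
#' Runs every generator in order (genome + reference annotation, novel
#' plants, triplex plant, expression truth, NB counts) and returns all
#' pipeline inputs with their ground truth. DE status is planted on
#' mRNAs and on lncRNAs (reference and novel), correlated DEL:DEG pairs
#' in the mated group, and the triplex TFO on the first planted class-u
#' lncRNA.
#'
#' @param config A [simulationConfig()].
#' @return List with \code{genome}, \code{reference}, \code{novel},
#'   \code{counts}, \code{sampleSheet}, \code{lengths}, and \code{truth}
#'   (list of per-stage truth tables: \code{transcripts}, \code{novel},
#'   \code{expression}, \code{pairs}, \code{triplex}).
#' @export
simulateStudy <- function(config = simulationConfig()) {
  ga <- simulateGenomeAnnotation(config)
  nv <- simulateNovelTranscripts(ga, config)
  ## triplex plant on the first class-u lncRNA (long enough for the TFO)
  uIds <- nv$truth$transcript_id[nv$truth$true_class == "u"]
  tri <- NULL
  if (length(uIds) && !is.na(.triplexHostGene(ga$reference, config$tractLength))) {
    lens <- splicedLength(nv$novel)[uIds]
    cand <- uIds[lens >= config$tractLength + 2]
    if (length(cand)) {
      tri <- plantTriplex(nv$genome, ga$reference, nv$novel, cand[1], config)
      nv$genome <- tri$genome
    }
  }
  ## expression truth
  set.seed(config$seed + 4000L)
  keptNovel <- nv$truth$transcript_id[nv$truth$true_class %in% c("i", "y", "p", "u")]
  feats <- c(txIds(ga$reference), keptNovel)
  kind <- c(txBiotype(ga$reference)[txIds(ga$reference)],
            stats::setNames(rep("novel", length(keptNovel)), keptNovel))
  G <- length(feats)
  means <- stats::setNames(
    exp(stats::runif(G, log(config$meanRange[1]), log(config$meanRange[2]))),
    feats)
  disp <- stats::runif(G, config$dispersionRange[1], config$dispersionRange[2])
  lfc <- stats::setNames(rep(0, G), feats)
  mIds <- feats[kind == "mRNA"]
  lIds <- feats[kind != "mRNA"]
  deM <- sample(mIds, min(config$nDeMrna, length(mIds)))
  deL <- sample(lIds, min(config$nDeLnc, length(lIds)))
  lfc[deM] <- config$plantedLog2FC *
    rep_len(c(1, -1), length(deM))
  lfc[deL] <- config$plantedLog2FC * rep_len(c(1, -1), length(deL))
  ## planted DE genes get solid expression so the calls are identifiable
  means[c(deM, deL)] <- exp(stats::runif(length(c(deM, deL)), log(200), log(1000)))
  if (!is.null(tri)) {
    ## the triplex story: lncRNA up in mated, its target mRNA repressed,
    ## strong negative co-expression in the mated group
    lfc[tri$truth$lncrna_id] <- config$plantedLog2FC
    means[tri$truth$lncrna_id] <- 500
    lfc[tri$truth$host_transcript] <- -config$plantedLog2FC
    means[tri$truth$host_transcript] <- 500
    deM <- union(deM, tri$truth$host_transcript)
    deL <- union(deL, tri$truth$lncrna_id)
  }
  nPairs <- min(config$nPairs, length(deL), length(deM))
  pairs <- if (nPairs > 0) data.frame(
    a = sample(deL, nPairs), b = sample(deM, nPairs),
    rho = config$targetRho * rep_len(c(1, -1), nPairs),
    group = "mated", stringsAsFactors = FALSE) else NULL
  if (!is.null(tri)) {
    pairs <- rbind(
      data.frame(a = tri$truth$lncrna_id, b = tri$truth$host_transcript,
                 rho = -abs(config$targetRho), group = "mated",
                 stringsAsFactors = FALSE),
      pairs[!(pairs$a == tri$truth$lncrna_id |
                pairs$b == tri$truth$host_transcript), , drop = FALSE])
  }
  cnt <- simulateCounts(means, lfc, disp, config, pairs = pairs)
  lengths <- c(splicedLength(ga$reference), splicedLength(nv$novel))
  exprTruth <- data.frame(feature_id = feats, kind = unname(kind[feats]),
                          mean = unname(means), log2FC = unname(lfc),
                          dispersion = disp,
                          de = lfc != 0, stringsAsFactors = FALSE)
  list(genome = nv$genome, reference = ga$reference, novel = nv$novel,
       counts = cnt$counts, sampleSheet = cnt$sampleSheet,
       lengths = lengths,
       truth = list(transcripts = ga$truth, novel = nv$truth,
                    expression = exprTruth, pairs = pairs,
                    triplex = if (is.null(tri)) NULL else tri$truth))
}

#' Write a simulated study to disk
#'
#' Emits genome.fasta, reference.gtf, novel.gtf, transcripts.fasta,
#' counts.tsv, samples.tsv, lengths.tsv and truth tables as plain text.
#'
#' @param study Output of [simulateStudy()].
#' @param dir Output directory (created if needed).
#' @return Invisibly, \code{dir}.
#' @export
writeStudy <- function(study, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  writeFasta(study$genome, file.path(dir, "genome.fasta"))
  writeGtf(study$reference, file.path(dir, "reference.gtf"))
  writeGtf(study$novel, file.path(dir, "novel.gtf"))
  seqs <- c(extractTxSeqs(study$reference, study$genome),
            extractTxSeqs(study$novel, study$genome))
  writeFasta(seqs, file.path(dir, "transcripts.fasta"))
  writeCountsTsv(study$counts, file.path(dir, "counts.tsv"))
  utils::write.table(study$sampleSheet, file.path(dir, "samples.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(
    data.frame(feature_id = names(study$lengths), length = study$lengths),
    file.path(dir, "lengths.tsv"), sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(study$truth$expression, file.path(dir, "truth_expression.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(study$truth$novel, file.path(dir, "truth_novel.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(dir)
}
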