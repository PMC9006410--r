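#' Spearman correlation with a t-approximation p-value
#'
#' Ranks with average ties, computes Pearson correlation on the ranks, and
#' tests two-sided via \code{t = rho * sqrt((n-2)/(1-rho^2))} with
#' \code{n - 2} degrees of freedom; \code{|rho| = 1} yields p = 0. For
#' \code{n <= 8} an exact permutation p-value over all \code{n!}
#' arrangements is available.
#'
#' @param x,y Numeric vectors of equal length (n >= 4), finite values.
#' @param exact Use exact permutation enumeration (only for n <= 8).
#' @return List with \code{rho} and \code{p}; zero-variance input gives
#'   \code{rho = NA}, \code{p = NA} with a \code{reason}.
#' @export
spearmanTest <- function(x, y, exact = FALSE) {
  n <- length(x)
  if (n != length(y)) stop("x and y must have equal length")
  if (n < 4) stop("need at least 4 observations")
  if (!all(is.finite(x)) || !all(is.finite(y))) stop("non-finite values")
  if (stats::var(x) == 0 || stats::var(y) == 0)
    return(list(rho = NA_real_, p = NA_real_, reason = "zero_variance"))
  rx <- rank(x); ry <- rank(y)
  rho <- stats::cor(rx, ry)
  if (exact) {
    if (n > 8) stop("exact enumeration supported for n <= 8 only")
    perms <- .permutations(n)
    obs <- abs(rho)
    cnt <- 0L
    for (i in seq_len(nrow(perms))) {
      r <- stats::cor(rx, ry[perms[i, ]])
      if (abs(r) >= obs - 1e-12) cnt <- cnt + 1L
    }
    return(list(rho = rho, p = cnt / nrow(perms)))
  }
  if (abs(rho) >= 1 - 1e-15) return(list(rho = rho, p = 0))
  tstat <- rho * sqrt((n - 2) / (1 - rho^2))
  list(rho = rho, p = 2 * stats::pt(-abs(tstat), df = n - 2))
}

.permutations <- function(n) {
  if (n == 1) return(matrix(1L, 1, 1))
  sub <- .permutations(n - 1L)
  do.call(rbind, lapply(seq_len(n), function(k) {
    cbind(k, sub + (sub >= k))
  }))
}

#' Build a per-group lncRNA:mRNA co-expression network
#'
#' Tests every DEL x DEG pair within each group's samples separately with
#' [spearmanTest()] and retains edges with \code{|rho| > rhoMin} (strict)
#' and \code{p < pMax} (strict). Raw p-values are used by default
#' (faithful to a raw-threshold convention but liberal); \code{adjust =
#' TRUE} applies BH across all pairs within each group first.
#'
#' @param tpm TPM matrix (features x samples).
#' @param dels,degs Disjoint id vectors of DE lncRNAs and DE mRNAs present
#'   in \code{tpm}.
#' @param sampleSheet data.frame with \code{sample_id} and \code{group}.
#' @param rhoMin,pMax Edge thresholds (defaults 0.8 and 0.01).
#' @param adjust Apply BH to edge p-values before thresholding.
#' @return data.frame of edges: \code{lncrna_id}, \code{mrna_id},
#'   \code{group}, \code{rho}, \code{p}, \code{sign}.
#' @export
buildNetwork <- function(tpm, dels, degs, sampleSheet, rhoMin = 0.8,
                         pMax = 0.01, adjust = FALSE) {
  if (length(intersect(dels, degs))) stop("DEL and DEG id sets must be disjoint")
  miss <- setdiff(c(dels, degs), rownames(tpm))
  if (length(miss)) stop("ids absent from tpm: ", paste(miss, collapse = ", "))
  idx <- match(colnames(tpm), sampleSheet$sample_id)
  groups <- sampleSheet$group[idx]
  out <- list()
  for (g in unique(groups)) {
    cols <- which(groups == g)
    n <- length(cols)
    if (n < 4) stop("group '", g, "' has fewer than 4 samples")
    rl <- t(apply(tpm[dels, cols, drop = FALSE], 1, rank))
    rm <- t(apply(tpm[degs, cols, drop = FALSE], 1, rank))
    zl <- rl - rowMeans(rl); zm <- rm - rowMeans(rm)
    den <- sqrt(rowSums(zl^2) %o% rowSums(zm^2))
    rho <- (zl %*% t(zm)) / den  # dels x degs; NaN for zero-variance rows
    tstat <- rho * sqrt((n - 2) / pmax(1 - rho^2, 1e-300))
    p <- 2 * stats::pt(-abs(tstat), df = n - 2)
    p[abs(rho) >= 1 - 1e-15] <- 0
    if (adjust) p[] <- bhAdjust(as.vector(p))
    keep <- which(!is.na(rho) & abs(rho) > rhoMin & p < pMax, arr.ind = TRUE)
    if (nrow(keep)) {
      out[[g]] <- data.frame(
        lncrna_id = dels[keep[, 1]], mrna_id = degs[keep[, 2]], group = g,
        rho = rho[keep], p = p[keep],
        sign = ifelse(rho[keep] > 0, "positive", "negative"),
        stringsAsFactors = FALSE)
    }
  }
  if (!length(out))
    return(data.frame(lncrna_id = character(0), mrna_id = character(0),
                      group = character(0), rho = numeric(0), p = numeric(0),
                      sign = character(0)))
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Cross-tabulate co-regulated pair categories
#'
#' Counts retained edges by (DEL direction x DEG direction) per group and
#' normalises to proportions within each group.
#'
#' @param edges Edge data.frame from [buildNetwork()].
#' @param deFlags Named character of DE flags (from [callDE()]) covering
#'   all edge endpoints.
#' @return data.frame with \code{group}, \code{del_direction},
#'   \code{deg_direction}, \code{n}, \code{proportion}.
#' @export
pairCategories <- function(edges, deFlags) {
  if (!nrow(edges))
    return(data.frame(group = character(0), del_direction = character(0),
                      deg_direction = character(0), n = integer(0),
                      proportion = numeric(0)))
  miss <- setdiff(unique(c(edges$lncrna_id, edges$mrna_id)), names(deFlags))
  if (length(miss)) stop("DE flags missing for: ", paste(miss, collapse = ", "))
  tab <- as.data.frame(table(
    group = edges$group,
    del_direction = deFlags[edges$lncrna_id],
    deg_direction = deFlags[edges$mrna_id]), stringsAsFactors = FALSE)
  colnames(tab)[4] <- "n"
  tab <- tab[tab$n > 0, , drop = FALSE]
  tot <- tapply(tab$n, tab$group, sum)
  tab$proportion <- tab$n / as.numeric(tot[tab$group])
  rownames(tab) <- NULL
  tab
}

#' Extract the ego network of one node
#'
#' @param edges Edge data.frame from [buildNetwork()].
#' @param focalId A lncRNA or mRNA id.
#' @param nodes Optional universe of known node ids; a focal id outside it
#'   is an error, while a known node without edges returns an empty set
#'   with a warning.
#' @return Subset of \code{edges} incident to the focal node.
#' @export
egoNetwork <- function(edges, focalId, nodes = NULL) {
  if (!is.null(nodes) && !focalId %in% nodes)
    stop("unknown node id: ", focalId)
  hit <- edges$lncrna_id == focalId | edges$mrna_id == focalId
  if (!any(hit)) warning("focal id '", focalId, "' has no incident edges")
  edges[hit, , drop = FALSE]
}
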