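## Family clustering, reference-family assignment, insertion dating and
## neighbour-joining phylogenetics.

#' Greedy centroid clustering of sequences
#'
#' Sequences are processed in order of decreasing length (ties keep
#' input order); each query joins the first existing centroid to which
#' its free-end-gap global identity (see [global_identity()]) reaches
#' `threshold`, otherwise it founds a new cluster. With
#' `strand_mode = "both"` the reverse complement is also tried and the
#' joining strand recorded. Deterministic.
#'
#' @param seqs named character vector of sequences (unique names).
#' @param threshold identity threshold (default 0.85).
#' @param strand_mode `"plus"` or `"both"`.
#' @return data frame with `centroid_id`, `member_id`, `strand`,
#'   `identity` (1 for the centroid itself), one row per sequence.
#' @export
cluster_greedy <- function(seqs, threshold = 0.85,
                           strand_mode = c("both", "plus")) {
  strand_mode <- match.arg(strand_mode)
  stopifnot(is.character(seqs), !is.null(names(seqs)))
  if (anyDuplicated(names(seqs)))
    stop("duplicate sequence ids: ",
         paste(unique(names(seqs)[duplicated(names(seqs))]), collapse = ", "))
  ord <- order(-nchar(seqs))  # stable: ties keep input order
  centroids <- character(0)
  rows <- list()
  for (i in ord) {
    id <- names(seqs)[i]
    assigned <- FALSE
    for (cid in centroids) {
      gi <- global_identity(seqs[[cid]], seqs[[i]], strand_mode)
      if (gi$identity >= threshold) {
        rows[[length(rows) + 1L]] <- data.frame(
          centroid_id = cid, member_id = id, strand = gi$strand,
          identity = gi$identity, stringsAsFactors = FALSE)
        assigned <- TRUE
        break
      }
    }
    if (!assigned) {
      centroids <- c(centroids, id)
      rows[[length(rows) + 1L]] <- data.frame(
        centroid_id = id, member_id = id, strand = "+", identity = 1,
        stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Assign elements to a reference-defined family
#'
#' Keeps the sequences whose full-length global identity to the
#' reference (both strands tried) is strictly greater than `threshold`.
#'
#' @param element_seqs named character vector of element sequences.
#' @param reference_seq the family reference sequence.
#' @param threshold identity threshold (default 0.85; strict `>`).
#' @return data frame with `id`, `identity`, `strand` for the members.
#' @export
assign_family <- function(element_seqs, reference_seq, threshold = 0.85) {
  stopifnot(nzchar(reference_seq))
  res <- lapply(names(element_seqs), function(id) {
    gi <- global_identity(reference_seq, element_seqs[[id]], "both")
    data.frame(id = id, identity = gi$identity, strand = gi$strand,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, res)
  out <- out[out$identity > threshold, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Date an element from its LTR divergence
#'
#' The two LTRs are aligned globally (plus strand), divergence is the
#' p-distance `1 - identity`, and the insertion age follows the
#' molecular clock `age = divergence / (2 * rate)`, with `rate` the
#' per-site per-year substitution rate (default 6.96e-9, the tomato
#' synonymous-site rate). With `correction = "JC"` the p-distance is
#' first transformed by the Jukes-Cantor multiple-hit correction.
#' Identity classes: `>= 0.98` is `"98-100"`, `[0.95, 0.98)` is
#' `"95-98"`, `[0.85, 0.95)` is `"85-95"`, below that unclassified
#' (`NA`).
#'
#' @param ltr5_seq,ltr3_seq LTR sequences (element orientation).
#' @param rate_r substitutions/site/year.
#' @param correction `"none"` (p-distance, default) or `"JC"`.
#' @return list of class `"age_estimate"`: `ltr_identity`, `divergence`,
#'   `rate_r`, `age_years`, `age_my`, `age_class`.
#' @export
#' @examples
#' date_element("ACGT", "ACGT")$age_my  # 0
date_element <- function(ltr5_seq, ltr3_seq, rate_r = 6.96e-9,
                         correction = c("none", "JC")) {
  correction <- match.arg(correction)
  stopifnot(nzchar(ltr5_seq), nzchar(ltr3_seq))
  gi <- global_identity(ltr5_seq, ltr3_seq, "plus")
  identity <- gi$identity
  div <- 1 - identity
  if (correction == "JC")
    div <- if (div >= 0.75) Inf else -0.75 * log(1 - 4 * div / 3)
  age_years <- div / (2 * rate_r)
  structure(list(ltr_identity = identity, divergence = div, rate_r = rate_r,
                 age_years = age_years, age_my = age_years / 1e6,
                 age_class = age_class(identity)),
            class = "age_estimate")
}

#' @export
print.age_estimate <- function(x, ...) {
  cat(sprintf("LTR identity %.4f -> divergence %.4f -> %.2f My (class %s)\n",
              x$ltr_identity, x$divergence, x$age_my,
              ifelse(is.na(x$age_class), "unclassified", x$age_class)))
  invisible(x)
}

#' LTR identity class
#'
#' @param identity numeric vector of LTR-pair identities in `[0, 1]`.
#' @return character vector: `"98-100"`, `"95-98"`, `"85-95"` or `NA`
#'   below 0.85.
#' @export
age_class <- function(identity) {
  out <- rep(NA_character_, length(identity))
  out[identity >= 0.85] <- "85-95"
  out[identity >= 0.95] <- "95-98"
  out[identity >= 0.98] <- "98-100"
  out
}

#' Date every element of an annotation
#'
#' @param annotation an `"ltr_annotation"` object.
#' @param genome the genome it was computed from.
#' @param rate_r substitutions/site/year.
#' @return data frame mirroring a dating report: `id`, `chrom`,
#'   `start`, `end`, `ltr_identity`, `age_my`, `age_class`.
#' @export
date_elements <- function(annotation, genome, rate_r = 6.96e-9) {
  l5 <- element_seqs(annotation, genome, "ltr5")
  l3 <- element_seqs(annotation, genome, "ltr3")
  el <- annotation$elements
  est <- lapply(seq_along(l5), function(i) date_element(l5[[i]], l3[[i]],
                                                        rate_r))
  data.frame(id = el$id, chrom = el$chrom, start = el$start, end = el$end,
             ltr_identity = vapply(est, `[[`, numeric(1), "ltr_identity"),
             age_my = vapply(est, `[[`, numeric(1), "age_my"),
             age_class = vapply(est, `[[`, character(1), "age_class"),
             stringsAsFactors = FALSE)
}

#' Tamura-Nei (TN93) distance between two aligned sequences
#'
#' Standard TN93 distance from the proportions of A<->G and C<->T
#' transitions and of transversions, with empirical base frequencies
#' averaged over both sequences. Alignment columns where either
#' sequence has a gap or `N` are dropped pairwise. Returns `Inf` (with
#' a `saturated` attribute) when any logarithm argument is
#' non-positive.
#'
#' @param a,b aligned, equal-length sequences.
#' @return distance in substitutions/site.
#' @export
tn93_distance <- function(a, b) {
  ca <- seq_chars(toupper(a)); cb <- seq_chars(toupper(b))
  if (length(ca) != length(cb))
    stop("sequences must be aligned to equal length")
  keep <- ca %in% c("A", "C", "G", "T") & cb %in% c("A", "C", "G", "T")
  ca <- ca[keep]; cb <- cb[keep]
  n <- length(ca)
  if (n == 0L) stop("no comparable columns")
  freq <- (table(factor(ca, c("A", "C", "G", "T"))) +
             table(factor(cb, c("A", "C", "G", "T")))) / (2 * n)
  gA <- freq[["A"]]; gC <- freq[["C"]]; gG <- freq[["G"]]; gT <- freq[["T"]]
  gR <- gA + gG; gY <- gC + gT
  diff <- ca != cb
  P1 <- sum(diff & ((ca == "A" & cb == "G") | (ca == "G" & cb == "A"))) / n
  P2 <- sum(diff & ((ca == "C" & cb == "T") | (ca == "T" & cb == "C"))) / n
  Q <- sum(diff) / n - P1 - P2
  w1 <- 1 - P1 * gR / (2 * gA * gG) - Q / (2 * gR)
  w2 <- 1 - P2 * gY / (2 * gC * gT) - Q / (2 * gY)
  w3 <- 1 - Q / (2 * gR * gY)
  if (any(!is.finite(c(w1, w2, w3))) || any(c(w1, w2, w3) <= 0))
    return(structure(Inf, saturated = TRUE))
  d <- -2 * gA * gG / gR * log(w1) - 2 * gC * gT / gY * log(w2) -
    2 * (gR * gY - gA * gG * gY / gR - gC * gT * gR / gY) * log(w3)
  unname(d)
}

#' Neighbour-joining tree from a distance matrix
#'
#' Classic Saitou-Nei agglomeration: at each step the pair minimising
#' the Q criterion is joined (ties resolved by the lexicographically
#' smallest label pair, labels of internal nodes being the smallest
#' leaf label they contain); negative branch lengths are clamped to 0
#' with the deficit added to the sibling branch. Returns an unrooted
#' Newick string with branch lengths to 6 decimals.
#'
#' @param distances symmetric numeric matrix with zero diagonal,
#'   `n >= 3`.
#' @param labels leaf labels (default from `rownames(distances)`).
#' @return Newick string (terminated by `;`).
#' @export
nj_tree <- function(distances, labels = rownames(distances)) {
  d <- as.matrix(distances)
  n <- nrow(d)
  stopifnot(n >= 3L, ncol(d) == n)
  if (any(abs(d - t(d)) > 1e-8)) stop("distance matrix must be symmetric")
  if (is.null(labels)) labels <- paste0("t", seq_len(n))
  if (any(!is.finite(d))) stop("non-finite distances (saturated pairs?)")
  newick <- labels     # current node representations
  key <- labels        # tie-break key: smallest leaf label in node
  repeat {
    m <- nrow(d)
    if (m == 3L) break
    R <- rowSums(d)
    Qm <- (m - 2) * d - outer(R, R, "+")
    diag(Qm) <- Inf
    qmin <- min(Qm)
    cand <- which(Qm - qmin <= 1e-12 * max(1, abs(qmin)), arr.ind = TRUE)
    cand <- cand[cand[, 1L] < cand[, 2L], , drop = FALSE]
    pair_key <- apply(cand, 1L, function(ij) {
      ks <- sort(c(key[ij[1L]], key[ij[2L]]))
      paste(ks, collapse = "\r")
    })
    pick <- cand[order(pair_key)[1L], ]
    i <- pick[[1L]]; j <- pick[[2L]]
    bi <- d[i, j] / 2 + (R[i] - R[j]) / (2 * (m - 2))
    bj <- d[i, j] - bi
    if (bi < 0) { bj <- bj + bi; bi <- 0 }
    if (bj < 0) { bi <- bi + bj; bj <- 0 }
    node <- sprintf("(%s:%.12f,%s:%.12f)", newick[i], bi, newick[j], bj)
    nkey <- min(key[i], key[j])
    du <- (d[i, ] + d[j, ] - d[i, j]) / 2
    keep <- setdiff(seq_len(m), c(i, j))
    d2 <- rbind(cbind(d[keep, keep, drop = FALSE], du[keep]),
                c(du[keep], 0))
    newick <- c(newick[keep], node)
    key <- c(key[keep], nkey)
    d <- d2
  }
  ## final trifurcation
  b1 <- (d[1, 2] + d[1, 3] - d[2, 3]) / 2
  b2 <- (d[1, 2] + d[2, 3] - d[1, 3]) / 2
  b3 <- (d[1, 3] + d[2, 3] - d[1, 2]) / 2
  b <- pmax(c(b1, b2, b3), 0)
  ord <- order(key)
  parts <- sprintf("%s:%.12f", newick, b)[ord]
  paste0("(", paste(parts, collapse = ","), ");")
}

#' Patristic distances between all leaves of a tree
#'
#' Path-length sums along branches, computed from a Newick string via
#' [ape::read.tree()].
#'
#' @param newick Newick string (with branch lengths) or a path is not
#'   accepted - pass text.
#' @return symmetric matrix of leaf-to-leaf path lengths with zero
#'   diagonal, rows/columns ordered by leaf label.
#' @export
patristic_distances <- function(newick) {
  tree <- tryCatch(suppressWarnings(ape::read.tree(text = newick)),
                   error = function(e) NULL)
  if (is.null(tree) || !inherits(tree, "phylo"))
    stop("malformed Newick string")
  if (is.null(tree$edge.length)) stop("Newick string has no branch lengths")
  d <- ape::cophenetic.phylo(tree)
  ord <- order(rownames(d))
  d[ord, ord, drop = FALSE]
}
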