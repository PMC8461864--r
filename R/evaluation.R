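#' Precision at K
#'
#' Fraction of the top-K ranked drugs that are known indications.
#'
#' @param ranked character vector of drug ids, best first.
#' @param gold character vector (or set) of indicated drug ids.
#' @param k cut-off; must satisfy `1 <= k <= length(ranked)` (no silent
#'   truncation).
#' @return a number in [0, 1].
#' @export
precisionAtK <- function(ranked, gold, k) {
    k <- asCount(k, "k")
    if (k < 1L || k > length(ranked))
        stop("k must be between 1 and the ranked-list length (",
             length(ranked), ")", call. = FALSE)
    sum(ranked[seq_len(k)] %in% gold) / k
}

#' Fold-enrichment of gold-standard drugs along a ranking
#'
#' Bins the ranked list into consecutive groups of `groupSize` from the top
#' (the final bin keeps the remainder) and computes, per group,
#' \deqn{FE = (n/m) / (N/M)}
#' where m is the group size, n the gold drugs in the group, M the ranked
#' universe size and N the gold drugs present in the ranking. Gold drugs
#' absent from the ranked universe are dropped with a message.
#'
#' @param ranked character vector of drug ids, best first.
#' @param gold character vector of indicated drug ids (nonempty after
#'   matching the ranked universe).
#' @param groupSize bin size (>= 1); 392 items at size 80 give bins
#'   80, 80, 80, 80, 72.
#' @return data.frame with columns `group`, `m`, `n`, `FE`.
#' @export
foldEnrichment <- function(ranked, gold, groupSize) {
    groupSize <- asCount(groupSize, "groupSize")
    if (groupSize < 1L) stop("groupSize must be >= 1", call. = FALSE)
    if (!length(ranked)) stop("ranked list is empty", call. = FALSE)
    gold <- unique(gold)
    present <- gold[gold %in% ranked]
    if (length(present) < length(gold))
        message(length(gold) - length(present),
                " gold drug(s) absent from the ranked universe; dropped")
    M <- length(ranked)
    N <- length(present)
    if (N == 0L)
        stop("no gold-standard drug present in the ranked universe",
             call. = FALSE)
    grp <- pmin(((seq_len(M) - 1L) %/% groupSize) + 1L,
                max(1L, ceiling(M / groupSize)))
    hit <- ranked %in% present
    m <- as.vector(table(grp))
    n <- as.vector(tapply(hit, grp, sum))
    data.frame(group = seq_along(m), m = m, n = n,
               FE = (n / m) / (N / M))
}

#' Linear trend of fold enrichment across rank groups
#'
#' Least-squares slope of the FE score against group order 1..G. A negative
#' slope means gold-standard density decays down the ranking, i.e. the score
#' concentrates known indications at the top.
#'
#' @param fe output of [foldEnrichment()] (needs at least 2 groups).
#' @return the slope (a single number).
#' @export
feTrend <- function(fe) {
    if (nrow(fe) < 2L)
        stop("need at least 2 groups to fit a trend", call. = FALSE)
    unname(stats::coef(stats::lm(FE ~ group, data = fe))[2L])
}

#' Spectral co-clustering of the score matrix
#'
#' Groups co-varying drugs and diseases simultaneously: the (min-shifted,
#' nonnegative) score matrix is normalized as
#' \eqn{A_n = D_1^{-1/2} A D_2^{-1/2}}, its leading singular vectors beyond
#' the trivial one are rescaled by \eqn{D^{-1/2}}, and rows and columns are
#' k-means clustered in that embedding (seeded, multiple restarts, so the
#' result is deterministic given the seed). A constant matrix carries no
#' structure and returns identity orders with a warning.
#'
#' @param sm a [ScoreMatrix-class].
#' @param nRowClusters,nColClusters cluster counts (each at most the
#'   corresponding dimension).
#' @param seed integer seed.
#' @return list with `rowOrder`, `colOrder` (permutations grouping members
#'   of a cluster together) and `rowLabels`, `colLabels` (named cluster
#'   memberships).
#' @export
biclusterScores <- function(sm, nRowClusters = 2L, nColClusters = 2L,
                            seed = 1L) {
    stopifnot(is(sm, "ScoreMatrix"))
    A <- sm@scores
    if (!nrow(A) || !ncol(A)) stop("empty score matrix", call. = FALSE)
    if (nRowClusters > nrow(A) || nColClusters > ncol(A))
        stop("cluster counts cannot exceed the matrix dimensions",
             call. = FALSE)
    rows <- rownames(A); cols <- colnames(A)
    if (max(A) == min(A)) {
        warning("constant score matrix; returning identity orders")
        return(list(rowOrder = seq_along(rows), colOrder = seq_along(cols),
                    rowLabels = setNames(rep(1L, length(rows)), rows),
                    colLabels = setNames(rep(1L, length(cols)), cols)))
    }
    A <- A - min(A)
    d1 <- pmax(rowSums(A), .Machine$double.eps)
    d2 <- pmax(colSums(A), .Machine$double.eps)
    An <- A / sqrt(d1) / rep(sqrt(d2), each = nrow(A))
    sv <- svd(An)
    l <- max(nRowClusters, nColClusters, 2L)
    take <- seq(2L, min(l, length(sv$d)))
    U <- sv$u[, take, drop = FALSE] / sqrt(d1)
    V <- sv$v[, take, drop = FALSE] / sqrt(d2)
    clusterSide <- function(emb, k) {
        if (k == 1L) return(rep(1L, nrow(emb)))
        if (k >= nrow(emb)) return(seq_len(nrow(emb)))
        keys <- apply(round(emb, 12L), 1L, paste, collapse = ",")
        if (length(unique(keys)) <= k)   # too few distinct points: group ties
            return(match(keys, unique(keys)))
        stats::kmeans(emb, k, nstart = 25L)$cluster
    }
    withSeed(seed, {
        rowLab <- clusterSide(U, nRowClusters)
        colLab <- clusterSide(V, nColClusters)
    })
    # relabel clusters by first appearance so the labels themselves are
    # deterministic, then order members by cluster and original position
    canon <- function(lab) match(lab, unique(lab))
    rowLab <- canon(rowLab); colLab <- canon(colLab)
    list(rowOrder = order(rowLab, seq_along(rowLab)),
         colOrder = order(colLab, seq_along(colLab)),
         rowLabels = setNames(rowLab, rows),
         colLabels = setNames(colLab, cols))
}
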