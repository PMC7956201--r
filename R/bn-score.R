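# BDeu family scoring and sparse candidate selection.

# Core score on a 1-based state matrix. child/parIdx are column indices.
.familyScoreRaw <- function(X, cards, child, parIdx, ess) {
    r <- cards[[child]]
    pc <- .parentConfigIndex(X, parIdx, cards)
    q <- pc$q
    joint <- (pc$idx - 1L) * r + X[, child]     # child state varies fastest
    Njk <- tabulate(joint, nbins = q * r)
    dim(Njk) <- c(r, q)
    Nj <- colSums(Njk)
    aj <- ess / q
    ajk <- ess / (q * r)
    nz <- which(Nj > 0L)                         # unseen configs contribute 0
    s <- sum(lgamma(aj) - lgamma(aj + Nj[nz]))
    njk <- Njk[, nz, drop = FALSE]
    pos <- njk > 0L
    # zero-count cells contribute lgamma(ajk) - lgamma(ajk) = 0
    s + sum(lgamma(ajk + njk[pos]) - lgamma(ajk))
}

.scoreCache <- function() new.env(hash = TRUE, parent = emptyenv())

.cachedFamilyScore <- function(cache, X, cards, child, parIdx, ess) {
    key <- paste0(child, "|", paste(sort(parIdx), collapse = ","))
    val <- cache[[key]]
    if (!is.null(val)) return(val)
    val <- .familyScoreRaw(X, cards, child, parIdx, ess)
    cache[[key]] <- val
    val
}

#' BDeu family score
#'
#' The log Bayesian-Dirichlet equivalent-uniform (BDeu) marginal likelihood
#' of one network family: with r child states, q parent configurations,
#' counts N_jk of child state k under parent configuration j, and
#' hyperparameters a_j = ess/q, a_jk = ess/(q r),
#' \deqn{\sum_j [\ln\Gamma(a_j) - \ln\Gamma(a_j + N_j)] +
#'       \sum_{j,k} [\ln\Gamma(a_{jk} + N_{jk}) - \ln\Gamma(a_{jk})].}
#' Parent configurations never observed contribute zero. The total network
#' score is the sum of family scores (score decomposability), and
#' Markov-equivalent DAGs receive identical totals (score equivalence).
#'
#' @param data a \linkS4class{DiscretizedCells}.
#' @param child child variable name.
#' @param parents character vector of parent names (possibly empty).
#' @param ess equivalent sample size of the Dirichlet prior.
#' @return log marginal likelihood (scalar).
#' @examples
#' d <- DiscretizedCells(matrix(c(0L, 1L), 1, 2, dimnames = list("A", NULL)))
#' familyScore(d, "A")          # counts (1,1), ess = 1: log(1/8)
#' @export
familyScore <- function(data, child, parents = character(), ess = 1) {
    ld <- .learnData(data)
    if (!ncol(data)) stop("data contains no cells")
    if (child %in% parents) stop("child must not be among its parents")
    idx <- match(c(child, parents), ld$vars)
    if (anyNA(idx))
        stop("unknown variable(s): ",
             paste(c(child, parents)[is.na(idx)], collapse = ", "))
    .familyScoreRaw(ld$X, ld$cards, idx[1L], idx[-1L], ess)
}

# Pairwise plug-in mutual information from discrete counts (natural log).
.pairMI <- function(xi, xj, ri, rj) {
    n <- length(xi)
    joint <- tabulate((xj - 1L) * ri + xi, nbins = ri * rj)
    dim(joint) <- c(ri, rj)
    pij <- joint / n
    pi_ <- rowSums(pij)
    pj_ <- colSums(pij)
    pos <- pij > 0
    sum(pij[pos] * log(pij[pos] / (pi_[row(pij)[pos]] * pj_[col(pij)[pos]])))
}

#' Sparse candidate parent sets
#'
#' For each variable, selects the \code{k} other variables with the highest
#' pairwise mutual information (plug-in estimate from the discretized
#' counts) as its candidate parent pool for the structure search. MI ties
#' are broken by variable name, so candidate sets are deterministic.
#' Variables in \code{forced} (contrast indicators) are placed in every
#' pool regardless of MI, so weak but real regime linkage cannot be masked
#' by the pruning.
#'
#' @param data a \linkS4class{DiscretizedCells}.
#' @param kCandidates pool size (must be below the number of variables).
#' @param forced variable names forced into every pool.
#' @return named list: for each variable, the character vector of its
#'   candidate parents.
#' @export
sparseCandidates <- function(data, kCandidates, forced = character()) {
    ld <- .learnData(data)
    p <- length(ld$vars)
    if (kCandidates >= p)
        stop("kCandidates must be below the number of variables")
    if (!all(forced %in% ld$vars))
        stop("forced variables not in data: ",
             paste(setdiff(forced, ld$vars), collapse = ", "))
    mi <- matrix(0, p, p, dimnames = list(ld$vars, ld$vars))
    for (i in seq_len(p - 1L)) for (j in (i + 1L):p) {
        mi[i, j] <- mi[j, i] <-
            .pairMI(ld$X[, i], ld$X[, j], ld$cards[[i]], ld$cards[[j]])
    }
    out <- vector("list", p)
    names(out) <- ld$vars
    for (v in ld$vars) {
        others <- setdiff(ld$vars, v)
        ord <- others[order(-mi[v, others], others)]
        out[[v]] <- union(intersect(forced, others),
                          utils::head(ord, kCandidates))
        out[[v]] <- sort(out[[v]])
    }
    out
}
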