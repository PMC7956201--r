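# Internal graph and indexing helpers shared across the package.

# parents: named list of character vectors; nodes: character
.hasCycle <- function(parents, nodes) {
    indeg <- vapply(nodes, function(v) length(parents[[v]]), 0L)
    children <- .childrenMap(parents, nodes)
    queue <- nodes[indeg == 0L]
    seen <- 0L
    while (length(queue)) {
        v <- queue[[1L]]; queue <- queue[-1L]
        seen <- seen + 1L
        for (ch in children[[v]]) {
            indeg[[ch]] <- indeg[[ch]] - 1L
            if (indeg[[ch]] == 0L) queue <- c(queue, ch)
        }
    }
    seen < length(nodes)
}

.childrenMap <- function(parents, nodes) {
    children <- stats::setNames(vector("list", length(nodes)), nodes)
    for (v in nodes) children[[v]] <- character()
    for (v in nodes) for (u in parents[[v]])
        children[[u]] <- c(children[[u]], v)
    children
}

.topoOrder <- function(parents, nodes) {
    indeg <- vapply(nodes, function(v) length(parents[[v]]), 0L)
    children <- .childrenMap(parents, nodes)
    queue <- nodes[indeg == 0L]
    out <- character()
    while (length(queue)) {
        v <- queue[[1L]]; queue <- queue[-1L]
        out <- c(out, v)
        for (ch in children[[v]]) {
            indeg[[ch]] <- indeg[[ch]] - 1L
            if (indeg[[ch]] == 0L) queue <- c(queue, ch)
        }
    }
    if (length(out) != length(nodes)) stop("graph contains a directed cycle")
    out
}

# Mixed-radix index of parent configurations, first parent fastest.
# X: n x p integer matrix of 1-based states; parIdx: integer column indices.
.parentConfigIndex <- function(X, parIdx, cards) {
    n <- nrow(X)
    if (!length(parIdx)) return(list(idx = rep.int(1L, n), q = 1L))
    idx <- numeric(n)
    stride <- 1
    for (p in parIdx) {
        idx <- idx + (X[, p] - 1L) * stride
        stride <- stride * cards[[p]]
    }
    if (stride > 5e6)
        stop("parent configuration space too large (", stride, " states)")
    list(idx = as.integer(idx) + 1L, q = as.integer(stride))
}

# Decode configuration j (1-based) into 1-based parent states.
.decodeConfig <- function(j, cards) {
    s <- integer(length(cards))
    j <- j - 1L
    for (i in seq_along(cards)) {
        s[i] <- j %% cards[i] + 1L
        j <- j %/% cards[i]
    }
    s
}

# 1-based state matrix (cells x vars) plus cardinalities, for the learners.
.learnData <- function(disc) {
    stopifnot(is(disc, "DiscretizedCells"))
    lab <- assay(disc, "labels")
    X <- t(lab) + 1L
    storage.mode(X) <- "integer"
    list(X = X, cards = unname(disc@nLevels[rownames(disc)]),
         vars = rownames(disc))
}

.edgeKey <- function(from, to) paste(from, to, sep = " -> ")

# Small deterministic seed derivation that stays inside 32-bit range.
.deriveSeed <- function(seed, offset) {
    as.integer((as.numeric(seed) * 7919 + offset) %% .Machine$integer.max)
}
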