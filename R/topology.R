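#' Signed, directed regulatory structure of an N-gene network
#'
#' A static GRN model: which gene regulates which, and whether the influence
#' is activating or inhibiting.  Self-edges are permitted; at most one edge
#' per ordered (source, target) pair.
#'
#' @param n_genes positive integer, number of genes.
#' @param edges data frame with columns `from`, `to` (gene indices in
#'   `1:n_genes`) and `sign` (`"activating"` or `"inhibiting"`, or `+1`/`-1`).
#' @return an object of class `grn_topology` with fields `n_genes` and
#'   `edges` (columns `from`, `to`, `sign` with sign coded `+1`/`-1`).
#' @export
grn_topology <- function(n_genes, edges = NULL) {
  if (!is.numeric(n_genes) || length(n_genes) != 1L || n_genes < 1 ||
      n_genes != round(n_genes)) {
    stop("n_genes must be a positive integer", call. = FALSE)
  }
  n_genes <- as.integer(n_genes)
  if (is.null(edges) || nrow(edges) == 0L) {
    edges <- data.frame(from = integer(), to = integer(), sign = integer())
  } else {
    edges <- as.data.frame(edges)
    stopifnot(all(c("from", "to", "sign") %in% names(edges)))
    if (is.character(edges$sign)) {
      s <- match(edges$sign, c("activating", "inhibiting"))
      if (anyNA(s)) stop("edge sign must be 'activating' or 'inhibiting'",
                         call. = FALSE)
      edges$sign <- c(1L, -1L)[s]
    }
    edges$from <- as.integer(edges$from)
    edges$to <- as.integer(edges$to)
    edges$sign <- as.integer(sign(edges$sign))
    if (any(edges$from < 1L | edges$from > n_genes |
            edges$to < 1L | edges$to > n_genes)) {
      stop("gene indices must lie in [1, n_genes]", call. = FALSE)
    }
    if (any(edges$sign == 0L)) stop("edge sign must be non-zero", call. = FALSE)
    if (anyDuplicated(edges[, c("from", "to")])) {
      stop("at most one edge per ordered (source, target) pair", call. = FALSE)
    }
    edges <- edges[order(edges$to, edges$from), c("from", "to", "sign")]
    rownames(edges) <- NULL
  }
  structure(list(n_genes = n_genes, edges = edges), class = "grn_topology")
}

#' @export
print.grn_topology <- function(x, ...) {
  cat("GRN topology:", x$n_genes, "genes,", nrow(x$edges), "edges\n")
  if (nrow(x$edges)) {
    arrows <- ifelse(x$edges$sign > 0, "->", "-|")
    cat(paste0("  X", x$edges$from, " ", arrows, " X", x$edges$to),
        sep = "\n")
  }
  invisible(x)
}

# incoming regulators of gene i, in ascending source order
regulators_of <- function(topology, i) {
  e <- topology$edges
  e[e$to == i, , drop = FALSE]
}

# n x n signed adjacency mask; mask[i, j] = sign of edge j -> i (0 if absent)
adjacency_mask <- function(topology) {
  n <- topology$n_genes
  m <- matrix(0L, n, n)
  e <- topology$edges
  if (nrow(e)) m[cbind(e$to, e$from)] <- e$sign
  m
}
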