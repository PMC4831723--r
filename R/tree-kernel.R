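#' Convolution tree kernels
#'
#' Collins-Duffy style convolution kernels over [struct_tree()] objects:
#' the subtree (ST) and subset-tree (SST) variants with decay `lambda`,
#' cosine normalization, and the SDF+SPF composite kernel used by the
#' tree-kernel classifier.
#'
#' @name tree_kernel
NULL

#' Tree-kernel configuration
#'
#' @param variant `"SST"` (subset trees; default) or `"ST"` (full subtrees).
#' @param lambda Decay factor in `(0, 1]` (default 0.4).
#' @param normalize Cosine-normalize each kernel (default `TRUE`).
#' @param composite_weights Length-2 weights for the SDF and SPF views in the
#'   composite kernel (default `c(1, 1)`).
#' @return A `cdr_kernel_config` list.
#' @export
kernel_config <- function(variant = c("SST", "ST"), lambda = 0.4,
                          normalize = TRUE, composite_weights = c(sdf = 1, spf = 1)) {
  variant <- match.arg(variant)
  stopifnot(lambda > 0, lambda <= 1, length(composite_weights) == 2L)
  structure(list(variant = variant, lambda = lambda, normalize = normalize,
                 composite_weights = composite_weights),
            class = "cdr_kernel_config")
}

# Flatten a tree into parallel vectors over internal (production) nodes, in
# post-order, with production strings "label -> child labels" and a
# preterminal flag (all children are leaves). Child slots map to flattened
# indices (NA for leaf children).
flatten_tree <- function(tree) {
  prods <- character(); preterm <- logical(); kids <- list()
  walk <- function(node) {               # returns flattened index or NA (leaf)
    if (is_leaf(node)) return(NA_integer_)
    child_ids <- vapply(node$children, walk, integer(1))
    labels <- vapply(node$children, function(c) c$label, character(1))
    prods[[length(prods) + 1L]] <<- paste(node$label, "->", paste(labels, collapse = " "))
    preterm[[length(preterm) + 1L]] <<- all(is.na(child_ids))
    kids[[length(kids) + 1L]] <<- child_ids
    length(prods)
  }
  walk(tree)
  list(prods = prods, preterm = preterm, kids = kids)
}

#' Convolution tree kernel between two trees
#'
#' `K(t1, t2) = sum over node pairs of Delta(n1, n2)` where `Delta = 0` when
#' productions differ, `Delta = lambda` for matching preterminal productions,
#' and otherwise `Delta = lambda * prod_i(sigma0 + Delta(c1i, c2i))` with
#' `sigma0 = 0` for the ST variant and `sigma0 = 1` for SST. Computed
#' bottom-up over the post-order node lists (memoized by construction).
#'
#' @param t1,t2 Non-empty `struct_tree` objects (or pre-flattened trees from
#'   the internal cache).
#' @param config A [kernel_config()].
#' @return A non-negative number.
#' @export
tree_kernel <- function(t1, t2, config = kernel_config()) {
  f1 <- if (inherits(t1, "struct_tree")) flatten_tree(t1) else t1
  f2 <- if (inherits(t2, "struct_tree")) flatten_tree(t2) else t2
  kernel_flat(f1, f2, config)
}

kernel_flat <- function(f1, f2, config) {
  sigma0 <- if (config$variant == "SST") 1 else 0
  lambda <- config$lambda
  n1 <- length(f1$prods); n2 <- length(f2$prods)
  delta <- matrix(0, n1, n2)
  match_mat <- outer(f1$prods, f2$prods, "==")
  for (i in seq_len(n1)) {
    js <- which(match_mat[i, ])
    if (!length(js)) next
    for (j in js) {
      if (f1$preterm[[i]]) {
        delta[i, j] <- lambda
      } else {
        k1 <- f1$kids[[i]]; k2 <- f2$kids[[j]]
        prod_term <- 1
        for (c in seq_along(k1)) {
          # matching production => identical child label sequences; a terminal
          # child is already fully matched by the production (factor 1),
          # a non-terminal child contributes sigma0 + Delta
          prod_term <- prod_term *
            (if (is.na(k1[[c]]) || is.na(k2[[c]])) 1
             else sigma0 + delta[k1[[c]], k2[[c]]])
        }
        delta[i, j] <- lambda * prod_term
      }
    }
  }
  sum(delta)
}

#' Cosine-normalized tree kernel
#'
#' `K(t1,t2) / sqrt(K(t1,t1) * K(t2,t2))`, in `[0, 1]`; 0 when either
#' self-kernel is 0.
#'
#' @inheritParams tree_kernel
#' @return A number in `[0, 1]`.
#' @export
normalized_kernel <- function(t1, t2, config = kernel_config()) {
  f1 <- if (inherits(t1, "struct_tree")) flatten_tree(t1) else t1
  f2 <- if (inherits(t2, "struct_tree")) flatten_tree(t2) else t2
  s1 <- kernel_flat(f1, f1, config); s2 <- kernel_flat(f2, f2, config)
  if (s1 == 0 || s2 == 0) return(0)
  kernel_flat(f1, f2, config) / sqrt(s1 * s2)
}

# a "view set" is list(sdf = struct_tree or NULL, spf = struct_tree or NULL);
# prepare_views pre-flattens and caches self-kernels for Gram computation
prepare_views <- function(views, config) {
  lapply(views, function(v) {
    lapply(v, function(tree) {
      if (is.null(tree)) return(NULL)
      f <- flatten_tree(tree)
      f$self <- kernel_flat(f, f, config)
      f
    })
  })
}

composite_prepared <- function(a, b, config) {
  w <- config$composite_weights
  total <- 0
  for (k in 1:2) {
    ta <- a[[k]]; tb <- b[[k]]
    if (is.null(ta) || is.null(tb)) next    # missing view contributes 0
    kv <- kernel_flat(ta, tb, config)
    if (config$normalize) {
      kv <- if (ta$self == 0 || tb$self == 0) 0 else kv / sqrt(ta$self * tb$self)
    }
    total <- total + w[[k]] * kv
  }
  total
}

#' Composite SDF+SPF kernel between two candidates
#'
#' Weighted sum of (normalized) tree kernels over the SDF and SPF views of
#' two candidates. A view missing on either side contributes 0 (with a
#' warning).
#'
#' @param views_a,views_b Lists `list(sdf = , spf = )` of `struct_tree`s
#'   (either may be `NULL` when the view is unavailable).
#' @param config A [kernel_config()].
#' @return A non-negative number.
#' @export
composite_kernel <- function(views_a, views_b, config = kernel_config()) {
  if (is.null(views_a$sdf) || is.null(views_b$sdf) ||
      is.null(views_a$spf) || is.null(views_b$spf)) {
    warning("missing tree view: it contributes 0 to the composite kernel", call. = FALSE)
  }
  p <- prepare_views(list(views_a[c("sdf", "spf")], views_b[c("sdf", "spf")]), config)
  composite_prepared(p[[1]], p[[2]], config)
}

#' Gram matrix of the composite kernel
#'
#' @param views_a,views_b Lists of view sets (`list(sdf=, spf=)` per
#'   candidate). When `views_b` is `NULL` the symmetric Gram of `views_a`
#'   with itself is computed.
#' @param config A [kernel_config()].
#' @return A numeric matrix `length(views_a) x length(views_b)`.
#' @export
gram_matrix <- function(views_a, views_b = NULL, config = kernel_config()) {
  pa <- prepare_views(views_a, config)
  symmetric <- is.null(views_b)
  pb <- if (symmetric) pa else prepare_views(views_b, config)
  K <- matrix(0, length(pa), length(pb))
  for (i in seq_along(pa)) {
    j0 <- if (symmetric) i else 1L
    for (j in j0:length(pb)) {
      K[i, j] <- composite_prepared(pa[[i]], pb[[j]], config)
      if (symmetric) K[j, i] <- K[i, j]
    }
  }
  K
}
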