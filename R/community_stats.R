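#' Build a samples-by-taxa composition matrix
#'
#' @param genes Gene table with taxonomy columns joined (one column per
#'   rank) and a `sample_id` column.
#' @param rank Taxonomic rank column to aggregate at.
#' @param abundance Optional named per-gene abundance (e.g. RPKM); default
#'   counts each gene once.
#' @return Numeric matrix, rows = samples, columns = taxa; unclassified
#'   genes are excluded.
#' @export
composition_matrix <- function(genes, rank = "order", abundance = NULL) {
  if (!rank %in% names(genes)) {
    abort(paste0("composition_matrix: no '", rank, "' column"))
  }
  g <- genes[!is.na(genes[[rank]]) & genes[[rank]] != "", ]
  w <- if (is.null(abundance)) rep(1, nrow(g)) else
    unname(abundance[g$gene_id])
  tab <- tapply(w, list(g$sample_id, g[[rank]]), sum, default = 0)
  m <- matrix(tab, nrow = nrow(tab),
              dimnames = list(rownames(tab), colnames(tab)))
  m
}

#' Bray-Curtis dissimilarity matrix
#'
#' `d(i,j) = sum |x_ik - x_jk| / sum (x_ik + x_jk)`, optionally after
#' closing each row to proportions (the default, so the measure reflects
#' composition rather than sequencing depth).
#'
#' @param m Non-negative numeric matrix, samples in rows.
#' @param close Divide each row by its total first (default TRUE).
#' @return Symmetric dissimilarity matrix with zero diagonal, values in
#'   `[0, 1]`.
#' @export
bray_curtis <- function(m, close = TRUE) {
  m <- as.matrix(m)
  if (any(m < 0)) abort("bray_curtis: negative abundances")
  rs <- rowSums(m)
  if (any(rs == 0)) {
    abort(paste0("bray_curtis: all-zero sample(s): ",
                 paste(rownames(m)[rs == 0], collapse = ", ")))
  }
  if (nrow(m) < 2) abort("bray_curtis: need at least 2 samples")
  if (close) m <- m / rs
  n <- nrow(m)
  d <- matrix(0, n, n, dimnames = list(rownames(m), rownames(m)))
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      d[i, j] <- d[j, i] <-
        sum(abs(m[i, ] - m[j, ])) / sum(m[i, ] + m[j, ])
    }
  }
  d
}

# Distance-based one-way sums of squares (Anderson's formulation):
# SS_total from all pairs over n; SS_within from within-group pairs over
# group sizes.
permanova_ss <- function(d2, grouping) {
  n <- nrow(d2)
  ss_total <- sum(d2[upper.tri(d2)]) / n
  ss_within <- 0
  for (g in unique(grouping)) {
    idx <- which(grouping == g)
    if (length(idx) > 1) {
      sub <- d2[idx, idx, drop = FALSE]
      ss_within <- ss_within + sum(sub[upper.tri(sub)]) / length(idx)
    }
  }
  c(total = ss_total, within = ss_within)
}

permanova_f <- function(d2, grouping) {
  a <- length(unique(grouping))
  n <- nrow(d2)
  ss <- permanova_ss(d2, grouping)
  ss_between <- ss["total"] - ss["within"]
  unname((ss_between / (a - 1)) / (ss["within"] / (n - a)))
}

#' One-way PERMANOVA on a dissimilarity matrix
#'
#' Permutational multivariate analysis of variance: the pseudo-F statistic
#' is computed from within- and between-group sums of squared
#' dissimilarities, and its significance from whole-sample permutations of
#' the group labels: `p = (1 + #(F_perm >= F_obs)) / (1 + n_permutations)`.
#'
#' @param d Symmetric dissimilarity matrix (e.g. from [bray_curtis()]).
#' @param grouping Group label per sample (same order as rows of `d`).
#' @param n_permutations Number of label permutations (default 999).
#' @param seed RNG seed for the permutations (default 20200213); always
#'   recorded in the result.
#' @return List of class `ibparch_permanova` with `pseudo_F`, `R2`,
#'   `p_value`, `df_between`, `df_within`, `n_permutations`, `seed`.
#' @export
permanova <- function(d, grouping, n_permutations = 999,
                      seed = 20200213) {
  d <- as.matrix(d)
  n <- nrow(d)
  if (length(grouping) != n) {
    abort("permanova: grouping length must match matrix dimension")
  }
  grouping <- as.character(grouping)
  a <- length(unique(grouping))
  if (a < 2) {
    abort("permanova: need at least 2 groups (degenerate design)")
  }
  if (n_permutations < 99) abort("permanova: n_permutations must be >= 99")
  d2 <- d^2
  ss <- permanova_ss(d2, grouping)
  if (ss["within"] <= 0) {
    abort("permanova: zero within-group sum of squares; F undefined")
  }
  f_obs <- permanova_f(d2, grouping)
  r2 <- unname((ss["total"] - ss["within"]) / ss["total"])
  exceed <- with_seed(seed, {
    sum(vapply(seq_len(n_permutations), function(k) {
      permanova_f(d2, sample(grouping))
    }, numeric(1)) >= f_obs)
  })
  structure(list(pseudo_F = f_obs, R2 = r2,
                 p_value = (1 + exceed) / (1 + n_permutations),
                 df_between = a - 1L, df_within = n - a,
                 n_permutations = as.integer(n_permutations),
                 seed = seed),
            class = "ibparch_permanova")
}

#' @export
print.ibparch_permanova <- function(x, ...) {
  cat(sprintf(
    "PERMANOVA (one-way): pseudo-F = %.3f (df %d, %d), R2 = %.3f, p = %.4g (%d permutations, seed %d)\n",
    x$pseudo_F, x$df_between, x$df_within, x$R2, x$p_value,
    x$n_permutations, x$seed))
  invisible(x)
}

#' Exact permutation p-value by exhaustive enumeration
#'
#' Enumerates every distinct assignment of the observed group sizes to
#' samples; practical only for small designs and used as a reference for
#' the sampled permutation test.
#'
#' @inheritParams permanova
#' @return List with `pseudo_F` and exact `p_value`.
#' @export
permanova_exact <- function(d, grouping) {
  d2 <- as.matrix(d)^2
  grouping <- as.character(grouping)
  n <- length(grouping)
  if (n > 12) abort("permanova_exact: exhaustive enumeration needs n <= 12")
  f_obs <- permanova_f(d2, grouping)
  perms <- all_label_permutations(grouping)
  fs <- vapply(perms, function(g) permanova_f(d2, g), numeric(1))
  list(pseudo_F = f_obs,
       p_value = mean(fs >= f_obs - 1e-12),
       n_assignments = length(perms))
}

# All distinct label assignments preserving group sizes (multiset
# permutations, built by choosing index sets per label iteratively).
all_label_permutations <- function(grouping) {
  labs <- unique(grouping)
  n <- length(grouping)
  sizes <- table(grouping)[labs]
  assignments <- list(rep(NA_character_, n))
  avail <- list(seq_len(n))
  for (k in seq_along(labs)) {
    new_assignments <- list(); new_avail <- list()
    combs <- NULL
    for (s in seq_along(assignments)) {
      av <- avail[[s]]
      cmb <- utils::combn(av, sizes[[k]], simplify = FALSE)
      for (cc in cmb) {
        a2 <- assignments[[s]]
        a2[cc] <- labs[k]
        new_assignments[[length(new_assignments) + 1L]] <- a2
        new_avail[[length(new_avail) + 1L]] <- setdiff(av, cc)
      }
    }
    assignments <- new_assignments
    avail <- new_avail
  }
  assignments
}
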