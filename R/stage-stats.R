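# Stage-stratified expression statistics: classical one-way ANOVA, planned
# contrasts on stage means, and the label-permutation empirical p-value
# Pr(F > f_obs). Low-level functions work on a value vector plus a stage
# factor; dataset-level wrappers extract a gene (within one group) first.

# Sums of squares pieces shared by the F statistic and the permutation
# engine. `G` is the 0/1 stage indicator matrix.
anova_pieces <- function(x, g) {
  g <- factor(g)
  if (nlevels(g) < 2) abort("need at least 2 factor levels")
  if (any(tabulate(g) == 0)) g <- droplevels(g)
  n <- length(x)
  G <- stats::model.matrix(~ 0 + g)
  ng <- colSums(G)
  grand <- sum(x)
  sst <- sum(x^2) - grand^2 / n
  list(g = g, G = G, ng = ng, n = n, k = nlevels(g), grand = grand, sst = sst)
}

#' One-way ANOVA F test on a vector
#'
#' Classical between/within mean-square ratio with p-value from the F
#' distribution. The degenerate case where both the between- and
#' within-group sums of squares are zero (all values identical) has an
#' undefined 0/0 statistic and raises an error.
#'
#' @param x Numeric response.
#' @param g Factor (or coercible) of the same length.
#' @return A tibble with `f`, `df_between`, `df_within`, `p`.
#' @export
f_oneway <- function(x, g) {
  pc <- anova_pieces(x, g)
  if (pc$n - pc$k < 1) abort("total within-group degrees of freedom must be >= 1")
  ssb <- sum(crossprod(pc$G, x)^2 / pc$ng) - pc$grand^2 / pc$n
  ssw <- pc$sst - ssb
  if (pc$sst <= .Machine$double.eps * max(1, pc$grand^2)) {
    abort("degenerate input: no variation between or within groups (F undefined)")
  }
  f <- (ssb / (pc$k - 1)) / (ssw / (pc$n - pc$k))
  tibble(
    f = max(f, 0),
    df_between = pc$k - 1L,
    df_within = pc$n - pc$k,
    p = pf(max(f, 0), pc$k - 1, pc$n - pc$k, lower.tail = FALSE)
  )
}

#' Planned contrast on factor-level means
#'
#' Single-degree-of-freedom contrast on the level means, using the pooled
#' within-group mean square from the full one-way model as the error term
#' (not a two-sample subset test), with a two-sided t test on the
#' within-group degrees of freedom.
#'
#' @param x Numeric response.
#' @param g Factor of the same length.
#' @param weights Named numeric contrast weights, names matching factor
#'   levels; must sum to zero. Levels not named get weight zero.
#' @return A tibble with `estimate`, `se`, `t`, `df`, `p`.
#' @export
contrast_oneway <- function(x, g, weights) {
  pc <- anova_pieces(x, g)
  if (is.null(names(weights))) abort("`weights` must be named by factor level")
  missing_lv <- setdiff(names(weights), levels(pc$g))
  if (length(missing_lv)) {
    abort(paste0("contrast references absent level(s): ", paste(missing_lv, collapse = ", ")))
  }
  if (abs(sum(weights)) > 1e-8) abort("contrast weights must sum to 0")
  w <- setNames(rep(0, pc$k), levels(pc$g))
  w[names(weights)] <- weights
  means <- as.numeric(crossprod(pc$G, x) / pc$ng)
  ssb <- sum(crossprod(pc$G, x)^2 / pc$ng) - pc$grand^2 / pc$n
  mse <- (pc$sst - ssb) / (pc$n - pc$k)
  est <- sum(w * means)
  se <- sqrt(mse * sum(w^2 / pc$ng))
  tstat <- if (se == 0 && est == 0) 0 else est / se
  tibble(
    estimate = est, se = se, t = tstat, df = pc$n - pc$k,
    p = 2 * pt(abs(tstat), pc$n - pc$k, lower.tail = FALSE)
  )
}

#' Permutation empirical p-value for the one-way F statistic
#'
#' Shuffles the stage labels over the samples (sampling without
#' replacement), recomputes the F statistic each time, and returns the
#' empirical p-value `Pr(F > f_obs)` — the fraction of permuted statistics
#' *strictly* exceeding the observed one. Ties with `f_obs` do not count as
#' exceedances, so a p-value of exactly 0 is possible; the optional add-one
#' smoothed estimator `(1 + #\{F >= f_obs\}) / (1 + n_perm)` never returns 0.
#'
#' @param x Numeric response.
#' @param g Factor of the same length.
#' @param n_perm Number of label permutations (default 1000).
#' @param seed Integer seed for the permutation stream.
#' @param smooth If TRUE, use the add-one smoothed estimator (default FALSE,
#'   the strict definition).
#' @return A tibble with `f_obs`, `p_empirical`, `n_perm`, `seed`.
#' @export
perm_f_pvalue <- function(x, g, n_perm = 1000, seed = 1, smooth = FALSE) {
  check_positive_int(n_perm, "n_perm")
  obs <- f_oneway(x, g)
  pc <- anova_pieces(x, g)
  dfb <- pc$k - 1
  dfw <- pc$n - pc$k
  withr::with_seed(seed, {
    idx <- vapply(seq_len(n_perm), function(i) sample.int(pc$n), integer(pc$n))
  })
  # permuting labels over samples == permuting values against fixed labels
  Xp <- matrix(x[idx], pc$n, n_perm)
  SSB <- colSums(crossprod(pc$G, Xp)^2 / pc$ng) - pc$grand^2 / pc$n
  Fp <- (SSB / dfb) / ((pc$sst - SSB) / dfw)
  # tie guard: a permutation reproducing the observed grouping recomputes F
  # with different floating-point rounding; without a tolerance such exact
  # ties would be counted as exceedances about half the time
  eps <- 1e-9 * max(1, abs(obs$f))
  p <- if (smooth) {
    (1 + sum(Fp >= obs$f - eps)) / (1 + n_perm)
  } else {
    sum(Fp > obs$f + eps) / n_perm
  }
  tibble(f_obs = obs$f, p_empirical = p, n_perm = as.integer(n_perm),
         seed = as.integer(seed))
}

#' Stage ANOVA for one gene of a dataset
#'
#' @param dataset An `expr_dataset` (normally log2-transformed first).
#' @param gene Gene id.
#' @param group Optional group label restricting the samples (the
#'   stage-stratified tests run within one group at a time).
#' @return A tibble with `gene_id`, `group`, `f`, `df_between`, `df_within`, `p`.
#' @export
anova_stage <- function(dataset, gene, group = NULL) {
  gv <- gene_vector(dataset, gene, group)
  bind_cols(tibble(gene_id = gene, group = group %||% "all"), f_oneway(gv$x, gv$stage))
}

#' Stage contrast for one gene of a dataset
#'
#' @inheritParams anova_stage
#' @param weights Named contrast weights over stage labels summing to zero,
#'   e.g. `c(normal = -1, I = 1)` for the Stage-I-vs-normal comparison.
#' @return A tibble with the contrast estimate (log2 units when the dataset
#'   is log2-transformed), `t`, `df` and two-sided `p`.
#' @export
stage_contrast <- function(dataset, gene, weights, group = NULL) {
  gv <- gene_vector(dataset, gene, group)
  bind_cols(tibble(gene_id = gene, group = group %||% "all"),
            contrast_oneway(gv$x, gv$stage, weights))
}

#' Permutation empirical p-value for one gene of a dataset
#'
#' @inheritParams anova_stage
#' @inheritParams perm_f_pvalue
#' @export
permutation_f_test <- function(dataset, gene, group = NULL, n_perm = 1000,
                               seed = 1, smooth = FALSE) {
  gv <- gene_vector(dataset, gene, group)
  bind_cols(tibble(gene_id = gene, group = group %||% "all"),
            perm_f_pvalue(gv$x, gv$stage, n_perm = n_perm, seed = seed, smooth = smooth))
}

#' Stage-stratified analysis over genes and groups
#'
#' Runs, for each requested (gene, group) pair: the one-way stage ANOVA, the
#' planned stage contrast, and (when `n_perm > 0`) the label-permutation
#' empirical p-value. Permutations shuffle stage labels only within the
#' analyzed group, never across groups. Each pair gets its own seed derived
#' deterministically from the master seed, so results do not depend on the
#' order in which pairs are computed.
#'
#' @param dataset An `expr_dataset`.
#' @param genes Character vector of gene ids (default: all genes).
#' @param groups Character vector of group labels (default: all groups).
#' @param contrast Named contrast weights over stages (default Stage I vs
#'   normal, `c(normal = -1, I = 1)`); set NULL to skip.
#' @param n_perm Permutations per test; 0 disables the empirical p-value and
#'   drops its columns (parametric-only report).
#' @param seed Master seed.
#' @param smooth Passed to [perm_f_pvalue()].
#' @return A `stage_test` tibble, one row per (gene, group), with columns
#'   `gene_id`, `group`, `f_obs`, `df_between`, `df_within`, `p_anova`,
#'   `contrast_estimate`, `p_contrast`, and when `n_perm > 0` also
#'   `p_empirical`, `n_perm`, `seed`.
#' @export
run_group_analysis <- function(dataset, genes = NULL, groups = NULL,
                               contrast = c(normal = -1, I = 1),
                               n_perm = 1000, seed = 1, smooth = FALSE) {
  stopifnot(inherits(dataset, "expr_dataset"))
  genes <- genes %||% dataset$values$gene_id
  groups <- groups %||% unique(dataset$meta$group)
  unknown <- setdiff(genes, dataset$values$gene_id)
  if (length(unknown)) {
    abort(paste0("unknown gene(s): ", paste(unknown, collapse = ", "),
                 "; available genes include: ",
                 paste(head(dataset$values$gene_id, 5), collapse = ", ")))
  }
  unknown_g <- setdiff(groups, unique(dataset$meta$group))
  if (length(unknown_g)) {
    abort(paste0("unknown group(s): ", paste(unknown_g, collapse = ", ")))
  }
  grid <- tidyr::expand_grid(gene_id = genes, group = groups)
  res <- pmap(list(grid$gene_id, grid$group, seq_len(nrow(grid))), function(gene, grp, i) {
    gv <- gene_vector(dataset, gene, grp)
    an <- f_oneway(gv$x, gv$stage)
    out <- tibble(
      gene_id = gene, group = grp,
      f_obs = an$f, df_between = an$df_between, df_within = an$df_within,
      p_anova = an$p
    )
    if (!is.null(contrast)) {
      ct <- contrast_oneway(gv$x, gv$stage, contrast)
      out$contrast_estimate <- ct$estimate
      out$p_contrast <- ct$p
    }
    if (n_perm > 0) {
      child <- derive_seed(seed, i)
      pe <- perm_f_pvalue(gv$x, gv$stage, n_perm = n_perm, seed = child, smooth = smooth)
      out$p_empirical <- pe$p_empirical
      out$n_perm <- pe$n_perm
      out$seed <- pe$seed
    }
    out
  })
  out <- bind_rows(res)
  class(out) <- c("stage_test", class(out))
  out
}

#' @method glance stage_test
#' @export
glance.stage_test <- function(x, ...) {
  tibble(
    n_tests = nrow(x),
    n_genes = dplyr::n_distinct(x$gene_id),
    n_groups = dplyr::n_distinct(x$group),
    n_anova_sig_05 = sum(x$p_anova <= 0.05),
    n_empirical_sig_05 = if ("p_empirical" %in% names(x)) sum(x$p_empirical <= 0.05) else NA_integer_
  )
}
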