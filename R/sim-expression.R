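# Synthetic expression generator: log2-normal baseline, additive stage/group
# shifts on the log scale, optional anti-correlated gene pairs through a
# shared latent factor. Everything is a pure function of its arguments plus
# the seed, and all planted structure is returned as truth tables.

#' Simulate a stage-annotated expression dataset
#'
#' Generates RPKM-like values as `2^(baseline + shift + latent + noise)`:
#' each gene gets a baseline drawn on the log2 scale, each cell adds
#' independent log2-scale noise (multiplicative on the raw scale), planted
#' genes add their configured per-(group, stage) shifts, and anti-correlated
#' pairs share a per-sample latent factor with opposite signs.
#'
#' @param n_genes Number of genes.
#' @param samples_per_stage Samples per stage within each group; either a
#'   single count or a named vector over `stages`.
#' @param stages Ordered stage labels (default the usual normal, I--IV).
#' @param groups Group (e.g. ancestry cohort) labels.
#' @param baseline_log_mean,baseline_log_sd Mean and SD of the per-gene
#'   baseline on the log2 scale.
#' @param noise_sd Per-cell log2-scale noise SD.
#' @param effects Planted effects: a data frame with columns `gene_id`,
#'   `group`, `stage`, `log2_shift` (additive on the log2 scale), or NULL.
#'   `gene_id`s must be among the generated ones (`g0001`, ...), or custom
#'   names which are assigned to the first rows.
#' @param anticorr_pairs Data frame with columns `gene1`, `gene2`, `rho`
#'   (target Pearson correlation on the log2 scale, in `[-1, 1]`), or NULL.
#' @param seed Integer seed; identical seeds give identical datasets.
#' @return An `expr_dataset`; planted structure is attached as
#'   `attr(x, "truth")`, a list with `effects` and `anticorr_pairs`.
#' @export
sim_expression <- function(n_genes = 100,
                           samples_per_stage = 10,
                           stages = c("normal", "I", "II", "III", "IV"),
                           groups = c("asian", "caucasian"),
                           baseline_log_mean = 5,
                           baseline_log_sd = 1,
                           noise_sd = 1,
                           effects = NULL,
                           anticorr_pairs = NULL,
                           seed = 1) {
  check_positive_int(n_genes, "n_genes")
  if (length(stages) < 2) abort("need at least 2 stage labels")
  if (length(samples_per_stage) == 1) {
    samples_per_stage <- setNames(rep(samples_per_stage, length(stages)), stages)
  }
  if (!setequal(names(samples_per_stage), stages)) {
    abort("`samples_per_stage` names must match `stages`")
  }
  if (any(samples_per_stage < 2)) abort("all stage sample counts must be >= 2")

  gene_ids <- sprintf("g%04d", seq_len(n_genes))
  if (!is.null(effects)) {
    effects <- as_tibble(effects)
    stopifnot(all(c("gene_id", "group", "stage", "log2_shift") %in% names(effects)))
    custom <- setdiff(unique(effects$gene_id), gene_ids)
    if (length(custom) > n_genes) abort("more planted genes than `n_genes`")
    gene_ids[seq_along(custom)] <- custom
    if (!all(effects$stage %in% stages)) {
      abort("invalid stage label in `effects`")
    }
    if (!all(effects$group %in% groups)) abort("invalid group label in `effects`")
  }
  if (!is.null(anticorr_pairs)) {
    anticorr_pairs <- as_tibble(anticorr_pairs)
    stopifnot(all(c("gene1", "gene2", "rho") %in% names(anticorr_pairs)))
    if (any(abs(anticorr_pairs$rho) > 1)) abort("`rho` must lie in [-1, 1]")
    if (!all(c(anticorr_pairs$gene1, anticorr_pairs$gene2) %in% gene_ids)) {
      abort("anticorr pair genes must be planted gene_ids")
    }
  }

  meta <- tidyr::expand_grid(group = groups, stage = stages) |>
    mutate(n = samples_per_stage[.data$stage]) |>
    tidyr::uncount(.data$n) |>
    mutate(sample_id = sprintf("s%04d", row_number())) |>
    select("sample_id", "stage", "group")
  n_samples <- nrow(meta)

  withr::with_seed(seed, {
    baseline <- rnorm(n_genes, baseline_log_mean, baseline_log_sd)
    log2mat <- matrix(rnorm(n_genes * n_samples, 0, noise_sd), n_genes, n_samples) + baseline

    if (!is.null(effects)) {
      key_mat <- paste(meta$group, meta$stage)
      for (i in seq_len(nrow(effects))) {
        gi <- match(effects$gene_id[i], gene_ids)
        cols <- key_mat == paste(effects$group[i], effects$stage[i])
        log2mat[gi, cols] <- log2mat[gi, cols] + effects$log2_shift[i]
      }
    }
    if (!is.null(anticorr_pairs)) {
      for (i in seq_len(nrow(anticorr_pairs))) {
        rho <- anticorr_pairs$rho[i]
        if (rho == 0) next
        # shared latent factor; coefficient chosen so the marginal log2
        # correlation of the pair is rho: a^2/(a^2 + noise_sd^2) = |rho|
        a <- noise_sd * sqrt(abs(rho) / (1 - abs(rho) + 1e-12))
        latent <- rnorm(n_samples)
        i1 <- match(anticorr_pairs$gene1[i], gene_ids)
        i2 <- match(anticorr_pairs$gene2[i], gene_ids)
        log2mat[i1, ] <- log2mat[i1, ] + a * latent
        log2mat[i2, ] <- log2mat[i2, ] + sign(rho) * a * latent
      }
    }
  })

  values <- as_tibble(2^log2mat, .name_repair = ~ meta$sample_id)
  values <- bind_cols(tibble(gene_id = gene_ids), values)
  out <- expr_dataset(values, meta)
  attr(out, "truth") <- list(
    effects = effects %||% tibble(gene_id = character(), group = character(),
                                  stage = character(), log2_shift = double()),
    anticorr_pairs = anticorr_pairs %||% tibble(gene1 = character(),
                                                gene2 = character(), rho = double())
  )
  out
}
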