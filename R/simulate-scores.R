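#' Specify a synthetic score simulation
#'
#' Class-conditional Gaussian raw scores per tool and category, with an
#' equicorrelated latent structure controlling how redundant the tools are
#' (one knob, `rho`, matching the high pairwise rank correlations real
#' nucleotide-level predictors exhibit). The default spec has five
#' categories, four informative tools whose class separation varies by
#' category (emulating category-specific score distributions), and one
#' label-independent noise tool mimicking a weak fitness-style score whose
#' inclusion should hurt the consensus.
#'
#' @param params Tibble with columns `tool`, `category`, `mean_d`, `sd_d`,
#'   `mean_n`, `sd_n` (one row per tool x category); defaults supplied when
#'   `NULL`.
#' @param specs Tool specs matching `params$tool`.
#' @param rho Equicorrelation of the latent Gaussian across tools, in
#'   \[0, 1).
#' @param n_per_class Variants per class per category (split evenly into
#'   train and test halves).
#' @param seed Integer seed; the simulation is a pure function of the spec
#'   and seed.
#' @return An object of class `score_sim_spec`.
#' @export
score_sim_spec <- function(params = NULL, specs = NULL, rho = 0.3,
                           n_per_class = 1000, seed = 1) {
  if (is.null(specs)) {
    specs <- tool_specs(
      tool_spec("toolA", "higher_is_deleterious"),
      tool_spec("toolB", "higher_is_deleterious"),
      tool_spec("toolC", "higher_is_deleterious"),
      tool_spec("toolD", "lower_is_deleterious"),
      tool_spec("noise", "higher_is_deleterious")
    )
  }
  validate_tool_specs(specs)
  if (is.null(params)) {
    params <- tidyr::expand_grid(tool = specs$tool, category = CATEGORIES) %>%
      mutate(
        # category-specific shift so optimal thresholds differ by category
        shift = dplyr::recode(.data$category, regulatory = 0, splicing = 0.1,
                              missense = 0.2, synonymous = -0.1, nonsense = 0.15),
        sep = dplyr::case_when(
          .data$tool == "noise" ~ 0,          # label-independent
          .data$tool == "toolA" ~ 0.4,
          .data$tool == "toolB" ~ 0.35,
          .data$tool == "toolC" ~ 0.3,
          TRUE ~ 0.25
        ),
        mean_d = 0.5 + .data$shift + .data$sep / 2,
        mean_n = 0.5 + .data$shift - .data$sep / 2,
        sd_d = 0.15, sd_n = 0.15
      ) %>%
      select("tool", "category", "mean_d", "sd_d", "mean_n", "sd_n")
    # mirror the polarity of the lower-is-deleterious tool
    flip <- params$tool %in% specs$tool[specs$polarity == "lower_is_deleterious"]
    tmp <- params$mean_d[flip]
    params$mean_d[flip] <- params$mean_n[flip]
    params$mean_n[flip] <- tmp
  }
  if (any(params$sd_d <= 0 | params$sd_n <= 0)) abort("standard deviations must be > 0")
  if (rho < 0 || rho >= 1) abort("rho must be in [0, 1)")
  structure(
    list(params = as_tibble(params), specs = specs, rho = rho,
         n_per_class = as.integer(n_per_class), seed = as.integer(seed)),
    class = "score_sim_spec"
  )
}

# Equicorrelated standard-normal draws: one shared factor plus independent
# noise per tool gives Corr(z_i, z_j) = rho for i != j.
equicorrelated_normal <- function(n, k, rho) {
  shared <- stats::rnorm(n)
  z <- matrix(stats::rnorm(n * k), n, k)
  sqrt(rho) * shared + sqrt(1 - rho) * z
}

#' Simulate labeled variants with per-tool raw scores
#'
#' Draws, for every category, `n_per_class` deleterious and `n_per_class`
#' neutral variants whose per-tool scores are Gaussian with the spec's
#' class-conditional parameters and equicorrelation `rho` across tools, then
#' splits each category in half into train and test (alternating, so both
#' halves stay exactly balanced). Deterministic under the spec's seed.
#'
#' @param spec A [score_sim_spec()].
#' @return A tibble: `chrom`, `pos`, `ref`, `alt`, `id`, `label`, `category`,
#'   `split` and one score column per tool, with the tool specs attached
#'   (a valid score table).
#' @export
simulate_scores <- function(spec) {
  stopifnot(inherits(spec, "score_sim_spec"))
  set.seed(spec$seed)
  tools <- spec$specs$tool
  k <- length(tools)
  out <- list()
  pos0 <- 0L
  for (cat in unique(spec$params$category)) {
    p <- spec$params[spec$params$category == cat, ]
    p <- p[match(tools, p$tool), ]
    rows <- list()
    for (lab in c("deleterious", "neutral")) {
      n <- spec$n_per_class
      z <- equicorrelated_normal(n, k, spec$rho)
      mu <- if (lab == "deleterious") p$mean_d else p$mean_n
      sd <- if (lab == "deleterious") p$sd_d else p$sd_n
      sc <- sweep(sweep(z, 2, sd, "*"), 2, mu, "+")
      colnames(sc) <- tools
      rows[[lab]] <- bind_cols(
        tibble(label = lab), as_tibble(sc)
      )
    }
    cat_tbl <- bind_rows(rows) %>%
      mutate(
        category = cat,
        chrom = "S1",
        pos = pos0 + dplyr::row_number(),
        ref = "A", alt = "G",
        id = sprintf("sim_%s_%d", cat, dplyr::row_number()),
        # alternate within each class so both halves stay balanced
        split = ifelse((dplyr::row_number() - 1) %% 2 == 0, "train", "test")
      )
    pos0 <- pos0 + nrow(cat_tbl)
    out[[cat]] <- cat_tbl
  }
  res <- bind_rows(out) %>%
    select("chrom", "pos", "ref", "alt", "id", "label", "category", "split",
           dplyr::all_of(tools))
  score_table(res, spec$specs)
}
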