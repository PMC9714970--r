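#' Two-sided Fisher exact test for a 2x2 table
#'
#' Implemented from first principles: with both margins fixed, the count in
#' cell (1,1) follows a hypergeometric distribution; the two-sided p-value is
#' the sum of the probabilities of all tables no more probable than the
#' observed one (the standard exact convention, as opposed to doubling the
#' one-sided tail). Probabilities are computed with `lchoose` for numerical
#' stability; a relative tolerance of 1e-7 guards the "no more probable"
#' comparison against rounding.
#'
#' @param tab 2x2 matrix of non-negative integer counts; rows = groups,
#'   columns = outcomes.
#' @return list of class `test_result`: `method`, `p_value`, `statistic`
#'   (sample odds ratio), `table`.
#' @export
fisher_exact_2x2 <- function(tab) {
  tab <- as.matrix(tab)
  if (!all(dim(tab) == c(2, 2))) stop("a 2x2 table is required")
  if (any(tab < 0) || any(tab != round(tab)))
    stop("counts must be non-negative integers")
  if (any(rowSums(tab) == 0) || any(colSums(tab) == 0))
    stop("both margins must be positive")
  a <- tab[1, 1]
  m <- sum(tab[1, ])          # row 1 total
  n <- sum(tab[2, ])          # row 2 total
  k <- sum(tab[, 1])          # column 1 total
  support <- max(0, k - n):min(k, m)
  logp <- lchoose(m, support) + lchoose(n, k - support) - lchoose(m + n, k)
  p_obs <- logp[match(a, support)]
  p <- sum(exp(logp[logp <= p_obs + 1e-7]))
  or <- (tab[1, 1] * tab[2, 2]) / (tab[1, 2] * tab[2, 1])
  structure(list(method = "Fisher exact (two-sided, sum of no-more-probable tables)",
                 p_value = min(p, 1), statistic = or, table = tab),
            class = "test_result")
}

#' @export
print.test_result <- function(x, ...) {
  cat(x$method, "\n")
  if (!is.null(x$statistic) && is.finite(x$statistic))
    cat("  statistic:", format(x$statistic), "\n")
  cat("  p-value:", format.pval(x$p_value, digits = 4), "\n")
  invisible(x)
}

#' Percent-of-control normalisation
#'
#' Each value is expressed as 100 times the value over the mean of the control
#' group; group summaries report mean and standard error of the mean
#' (sd with the n-1 denominator over the square root of n).
#'
#' @param values numeric measurements.
#' @param control_values numeric control-group measurements; their mean must
#'   be positive.
#' @param groups optional factor splitting `values` for the summary.
#' @return list: `percent` (per value), `summary` data.frame of group,
#'   n, mean_pct, sem_pct.
#' @export
percent_of_control <- function(values, control_values, groups = NULL) {
  cm <- mean(control_values)
  if (!is.finite(cm) || cm <= 0)
    stop("control mean must be positive (got ", format(cm), ")")
  pct <- 100 * values / cm
  if (is.null(groups)) groups <- rep("all", length(values))
  groups <- as.factor(groups)
  sm <- do.call(rbind, lapply(levels(groups), function(g) {
    v <- pct[groups == g]
    data.frame(group = g, n = length(v), mean_pct = mean(v),
               sem_pct = stats::sd(v) / sqrt(length(v)),
               stringsAsFactors = FALSE)
  }))
  list(percent = pct, summary = sm)
}

#' Uniform interface to standard two-group and k-group comparisons
#'
#' Thin wrapper delegating to the standard routines (Welch t, Mann-Whitney,
#' one-way ANOVA, Kruskal-Wallis); only the Fisher exact test is implemented
#' in this package from first principles.
#'
#' @param values numeric measurements.
#' @param groups factor of group labels.
#' @param method one of "welch", "wilcoxon", "anova", "kruskal".
#' @return a `test_result`.
#' @export
group_compare <- function(values, groups,
                          method = c("welch", "wilcoxon", "anova", "kruskal")) {
  method <- match.arg(method)
  groups <- as.factor(groups)
  res <- switch(method,
    welch = {
      t <- stats::t.test(values ~ groups)
      list(m = "Welch two-sample t-test", s = unname(t$statistic),
           p = t$p.value)
    },
    wilcoxon = {
      t <- stats::wilcox.test(values ~ groups)
      list(m = "Mann-Whitney (Wilcoxon rank-sum)", s = unname(t$statistic),
           p = t$p.value)
    },
    anova = {
      f <- stats::anova(stats::aov(values ~ groups))
      list(m = "one-way ANOVA", s = f$`F value`[1], p = f$`Pr(>F)`[1])
    },
    kruskal = {
      t <- stats::kruskal.test(values, groups)
      list(m = "Kruskal-Wallis", s = unname(t$statistic), p = t$p.value)
    })
  structure(list(method = res$m, p_value = res$p, statistic = res$s,
                 n = as.vector(base::table(groups))),
            class = "test_result")
}

# --- configuration-driven runner --------------------------------------------

.known_stages <- c("phantom", "quantify", "vesicles", "fisher")

#' Run a configured multi-stage analysis
#'
#' Executes the declared stages in order, writing one CSV/JSON artifact per
#' stage plus a provenance record (parameters, seed, package version). The
#' configuration is validated before any stage runs; identical configuration
#' and seed give bit-identical tables. Supported stages:
#' \describe{
#'   \item{phantom}{render a phantom stack ([simulate_stack()]); parameters
#'     are passed to [phantom_spec()]; writes `stack.tif` + ground truth.}
#'   \item{quantify}{ROI quantification of the phantom stack
#'     ([quantify_roi()]); fields `channel`, optional `roi` (origin/extent).}
#'   \item{vesicles}{enlarged-vesicle calls on the ground-truth lysosome
#'     mask ([detect_vesicles()]); field `diameter_threshold_um`.}
#'   \item{fisher}{[fisher_exact_2x2()] on a table given as `counts`
#'     (list of 4: a, b, c, d) or built from the vesicle stage's per-cell
#'     flags split by `groups`.}
#' }
#'
#' @param config path to a YAML/JSON file or an equivalent list with fields
#'   `seed` and `stages` (named list: stage name -> parameter list).
#' @param out_dir output directory, created if needed.
#' @return list of per-stage results, invisibly; artifacts in `out_dir`.
#' @export
run_config <- function(config, out_dir) {
  if (is.character(config)) {
    config <- if (grepl("\\.json$", config))
      jsonlite::read_json(config, simplifyVector = TRUE)
    else yaml::read_yaml(config)
  }
  stages <- config$stages
  if (is.null(stages) || !length(stages)) stop("config declares no stages")
  bad <- setdiff(names(stages), .known_stages)
  if (length(bad))
    stop("unknown stage(s) before run: ", paste(bad, collapse = ", "),
         "; supported: ", paste(.known_stages, collapse = ", "))
  seed <- config$seed %||% 1L
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  results <- list()
  state <- list()
  for (nm in names(stages)) {
    par <- stages[[nm]]
    if (identical(par, "")) par <- list()
    if (nm == "phantom") {
      par$seed <- par$seed %||% seed
      spec <- do.call(phantom_spec, par)
      sim <- simulate_stack(spec)
      write_stack(sim$stack, file.path(out_dir, "stack.tif"))
      write_ground_truth(sim$truth, file.path(out_dir, "truth.json"))
      state$sim <- sim
      results$phantom <- list(n_cells = spec$n_cells,
                              channels = sim$stack$channel_names)
    } else if (nm == "quantify") {
      if (is.null(state$sim)) stop("quantify stage needs a phantom stage first")
      roi <- if (!is.null(par$roi))
        roi_box(unlist(par$roi$origin_um), unlist(par$roi$extent_um))
      else NULL
      tabl <- quantify_group_stacks(list(phantom = state$sim$stack), roi = roi,
                                    channel = par$channel %||% 1)
      utils::write.csv(tabl, file.path(out_dir, "quantify.csv"),
                       row.names = FALSE)
      results$quantify <- tabl
    } else if (nm == "vesicles") {
      if (is.null(state$sim)) stop("vesicles stage needs a phantom stage first")
      mask <- truth_mask(state$sim$truth, "lysosomes")
      calls <- detect_vesicles(mask, state$sim$truth$voxel_size,
                               par$diameter_threshold_um %||% 2.0)
      utils::write.csv(calls, file.path(out_dir, "vesicles.csv"),
                       row.names = FALSE)
      results$vesicles <- calls
      state$calls <- calls
    } else if (nm == "fisher") {
      tab <- if (!is.null(par$counts))
        matrix(unlist(par$counts), 2, 2, byrow = TRUE)
      else stop("fisher stage requires 'counts' (a, b, c, d; rows = groups)")
      ft <- fisher_exact_2x2(tab)
      jsonlite::write_json(list(method = ft$method, p_value = ft$p_value,
                                table = ft$table),
                           file.path(out_dir, "fisher.json"),
                           auto_unbox = TRUE, digits = NA, matrix = "rowmajor")
      results$fisher <- ft
    }
  }
  prov <- list(package = "bundlequant",
               version = as.character(utils::packageVersion("bundlequant")),
               seed = seed, stages = stages)
  jsonlite::write_json(prov, file.path(out_dir, "provenance.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(results)
}
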