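# End-to-end cohorts: simulate groups of individuals (wild-type vs
# mutant), measure every applicable metric, and compare groups per
# metric — the desk-scale analogue of a phenotyping screen.

#' Specification of a simulated cohort
#'
#' Each group carries one simulation parameter set ([heart_sim_params()],
#' [flow_sim_params()] or [vessel_sim_params()]); individual i of the
#' cohort receives seed `base_seed + i` (assigned in enumeration order),
#' so re-running the same spec reproduces every number bit-exactly while
#' individuals stay independent.
#'
#' @param groups Named list (>= 2 entries) of simulation parameter sets,
#'   all of the same kind. The first group is the reference (wild type).
#' @param n_per_group Individuals per group (scalar or per-group vector,
#'   each >= 3).
#' @param base_seed Integer base seed.
#' @return An object of class `cohort_spec`.
#' @seealso [run_cohort()]
#' @export
cohort_spec <- function(groups, n_per_group, base_seed = 1) {
  if (!is.list(groups) || length(groups) < 2L)
    zf_stop("cohort", "need at least 2 groups")
  if (is.null(names(groups)) || any(names(groups) == ""))
    zf_stop("cohort", "groups must be named")
  kinds <- vapply(groups, function(g) class(g)[1], character(1))
  if (!all(kinds %in% c("heart_sim_params", "flow_sim_params",
                        "vessel_sim_params")) || length(unique(kinds)) != 1L)
    zf_stop("cohort", "groups must all hold one kind of *_sim_params")
  n_per_group <- rep_len(as.integer(n_per_group), length(groups))
  if (any(n_per_group < 3L))
    zf_stop("cohort", "need n >= 3 per group")
  structure(list(groups = groups, n_per_group = n_per_group,
                 base_seed = as.integer(base_seed), kind = kinds[1]),
            class = "cohort_spec")
}

# Simulate + measure one individual; returns a named numeric vector.
measure_individual <- function(params) {
  if (inherits(params, "heart_sim_params")) {
    sim <- simulate_heart_video(params)
    rep <- cardiac_report(sim$video)
    c(hr_bpm = rep$hr_bpm, edv_um3 = rep$edv_um3, esv_um3 = rep$esv_um3,
      sv_um3 = rep$sv_um3, co_nl_min = rep$co_nl_min, sf_pct = rep$sf_pct,
      ef_pct = rep$ef_pct, fac_pct = rep$fac_pct)
  } else if (inherits(params, "flow_sim_params")) {
    sim <- simulate_flow_video(params)
    disp_px <- params$velocity * (1 + params$pulsatility) /
      (params$fps * params$pixel_size)
    rep <- flow_report(sim$video, mode = params$mode,
                       max_disp = max(15, 2 * disp_px))
    c(velocity_um_s = rep$mean_velocity)
  } else {
    sim <- simulate_vessel_stack(params)
    seg <- select_structure(segment_vessels(sim$stack))
    c(vessel_volume_um3 = vessel_volume(seg)$volume_um3)
  }
}

#' Run a simulated cohort end to end
#'
#' For every individual the group's generator is run with its own seed,
#' all applicable metrics are measured with the standard measurement
#' chain, and each metric is compared between the reference (first) group
#' and every other group with [compare_groups()]. Individuals whose
#' measurement fails are recorded and skipped; the cohort errors if any
#' group drops below 3 usable individuals.
#'
#' @param spec A [cohort_spec()].
#' @param policy Test-selection policy passed to [compare_groups()].
#' @return A `cohort_result`: `results` (one row per individual: group,
#'   individual, seed, metric columns), `comparisons` (per metric, per
#'   non-reference group), `errors`, and the echoed `spec`.
#' @export
run_cohort <- function(spec, policy = "auto") {
  stopifnot(inherits(spec, "cohort_spec"))
  rows <- list()
  errors <- list()
  idx <- 0L
  for (g in seq_along(spec$groups)) {
    gname <- names(spec$groups)[g]
    for (i in seq_len(spec$n_per_group[g])) {
      idx <- idx + 1L
      params <- spec$groups[[g]]
      params$seed <- spec$base_seed + idx
      m <- tryCatch(measure_individual(params), zfcardio_error = identity)
      if (inherits(m, "condition")) {
        errors[[length(errors) + 1L]] <-
          data.frame(group = gname, individual = i, seed = params$seed,
                     error = conditionMessage(m))
      } else {
        rows[[length(rows) + 1L]] <-
          cbind(data.frame(group = gname, individual = i,
                           seed = params$seed), as.data.frame(t(m)))
      }
    }
  }
  results <- do.call(rbind, rows)
  usable <- table(factor(results$group, levels = names(spec$groups)))
  if (any(usable < 3L))
    zf_stop("cohort", "group '%s' has fewer than 3 usable individuals",
            names(usable)[which(usable < 3L)[1]])

  metrics <- setdiff(names(results), c("group", "individual", "seed"))
  ref <- names(spec$groups)[1]
  comparisons <- list()
  for (m in metrics) {
    comparisons[[m]] <- list()
    for (gname in names(spec$groups)[-1]) {
      va <- results[results$group == ref, m]
      vb <- results[results$group == gname, m]
      va <- va[is.finite(va)]; vb <- vb[is.finite(vb)]
      comparisons[[m]][[gname]] <- compare_groups(va, vb, policy = policy)
    }
  }
  structure(list(results = results, comparisons = comparisons,
                 errors = if (length(errors)) do.call(rbind, errors),
                 spec = spec),
            class = "cohort_result")
}

#' @export
print.cohort_result <- function(x, ...) {
  grp <- unique(x$results$group)
  metrics <- names(x$comparisons)
  cat(sprintf("Cohort: %d individuals in %d groups (reference: %s)\n",
              nrow(x$results), length(grp), grp[1]))
  if (!is.null(x$errors))
    cat(sprintf("  %d individuals failed and were skipped\n", nrow(x$errors)))
  for (m in metrics) {
    line <- sprintf("  %-16s", m)
    for (g in grp) {
      v <- x$results[x$results$group == g, m]
      line <- paste0(line, sprintf(" %s: %.4g +/- %.4g", g, mean(v), sd(v)))
    }
    ps <- vapply(x$comparisons[[m]], function(cmp) cmp$p_two_tailed,
                 numeric(1))
    line <- paste0(line, sprintf("  p = %s",
                                 paste(sprintf("%.3g", ps), collapse = ", ")))
    cat(line, "\n")
  }
  invisible(x)
}

#' @export
summary.cohort_result <- function(object, ...) {
  print(object)
  cat("\nTest trail:\n")
  for (m in names(object$comparisons))
    for (g in names(object$comparisons[[m]]))
      cat(sprintf("  %s vs %s [%s]: %s, p = %.4g\n", m, g,
                  object$comparisons[[m]][[g]]$policy,
                  object$comparisons[[m]][[g]]$test_used,
                  object$comparisons[[m]][[g]]$p_two_tailed))
  invisible(object)
}
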