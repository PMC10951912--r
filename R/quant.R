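# Delta-delta-Ct enrichment quantification and end-to-end orchestration.

#' Fold enrichment by the delta-delta-Ct method
#'
#' Per sample, `delta_ct = mean Ct(target) - mean Ct(iLAD reference)`
#' (technical replicates averaged on the cycle scale). Within each condition,
#' `delta_delta_ct = delta_ct(sample) - delta_ct(control sample)` where the
#' control sample expresses the untargeted construct (or is named
#' explicitly), and `fold = 2^(-delta_delta_ct)` under the ~100% amplification
#' efficiency assumption. Condition-level folds (mean over the condition's
#' non-control samples) are normalized to a named control condition, whose
#' normalized fold is exactly 1.
#'
#' @param table Ct table: data.frame with columns `sample_id, construct,
#'   condition, region, ct, replicate` (see [make_qpcr_table()]).
#' @param target Target region (e.g. `"telomere"`, a LAD name).
#' @param ilad_reference Reference inter-LAD region present in every sample.
#' @param control_sample Explicit control sample id; if `NULL`, each
#'   condition's sample with `construct == control_construct` is used.
#' @param control_condition Condition whose fold normalizes the others
#'   (never inferred; `NULL` skips normalization).
#' @param control_construct Construct treated as the within-condition
#'   control when `control_sample` is `NULL`.
#' @return An `enrichment_result`: `target`, `reference`, `per_sample`
#'   (sample_id, condition, delta_ct, delta_delta_ct, fold) and
#'   `per_condition` (condition, fold, normalized_fold).
#' @export
ddct_enrichment <- function(table, target, ilad_reference = "iLAD-SMIM2",
                            control_sample = NULL, control_condition = NULL,
                            control_construct = "M.EcoGII") {
  need <- c("sample_id", "condition", "region", "ct")
  if (!all(need %in% names(table)))
    stop("Ct table must have columns ", paste(need, collapse = ", "))
  if (any(table$ct <= 0)) stop("Ct values must be positive cycles")
  if (!target %in% table$region) stop("target region absent: ", target)
  if (!ilad_reference %in% table$region)
    stop("iLAD reference region absent: ", ilad_reference)

  mean_ct <- function(sid, reg) {
    v <- table$ct[table$sample_id == sid & table$region == reg]
    if (!length(v)) return(NA_real_)
    mean(v)
  }
  samples <- unique(table[, c("sample_id", "condition",
                              intersect("construct", names(table)))])
  samples$delta_ct <- vapply(samples$sample_id, function(sid)
    mean_ct(sid, target) - mean_ct(sid, ilad_reference), numeric(1))
  if (any(is.na(samples$delta_ct)))
    stop("some samples lack the target or reference region")

  ctrl_dct <- function(cond) {
    if (!is.null(control_sample)) {
      i <- match(control_sample, samples$sample_id)
      if (is.na(i)) stop("control sample absent: ", control_sample)
      return(samples$delta_ct[i])
    }
    i <- which(samples$condition == cond &
               samples$construct == control_construct)
    if (!length(i))
      stop("no control-construct sample in condition: ", cond)
    mean(samples$delta_ct[i])
  }
  samples$delta_delta_ct <- samples$delta_ct -
    vapply(samples$condition, ctrl_dct, numeric(1))
  samples$fold <- 2^(-samples$delta_delta_ct)

  is_ctrl_row <- if (!is.null(control_sample))
    samples$sample_id == control_sample
  else samples$construct == control_construct
  per_cond <- do.call(rbind, lapply(split(samples[!is_ctrl_row, ],
                                          samples$condition[!is_ctrl_row]),
    function(g) data.frame(condition = g$condition[1],
                           fold = mean(g$fold))))
  if (!is.null(control_condition)) {
    i <- match(control_condition, per_cond$condition)
    if (is.na(i)) stop("control condition absent: ", control_condition)
    per_cond$normalized_fold <- per_cond$fold / per_cond$fold[i]
  } else {
    per_cond$normalized_fold <- NA_real_
  }
  rownames(per_cond) <- NULL
  structure(list(target = target, reference = ilad_reference,
                 per_sample = samples, per_condition = per_cond),
            class = "enrichment_result")
}

#' @export
print.enrichment_result <- function(x, ...) {
  cat(sprintf("<enrichment_result> %s vs %s\n", x$target, x$reference))
  print(x$per_condition)
  invisible(x)
}

#' Run the full spatial analysis over a cohort of nuclei
#'
#' For each nucleus (an [object_pattern()] carrying its shape and stage
#' label): SDIs for the requested distance functions under the requested
#' null models, polarity indices along all three principal axes, and the
#' peripheral fraction at the given cutoff. Population-level KS uniformity
#' tests are computed per (stage, function, model) when at least 5 nuclei
#' contribute. Per-nucleus failures are isolated, recorded and do not stop
#' the run. Deterministic given `seed`.
#'
#' @param patterns List of [object_pattern()]s.
#' @param kinds Distance-function kinds to compute.
#' @param models Named list of [null_model_spec()]s (seeds inside are
#'   ignored; per-nucleus seeds derive from `seed`).
#' @param cutoff_um Peripheral cutoff (µm).
#' @param n_sims Simulations per SDI.
#' @param seed Master seed.
#' @return A `spatial_bundle`: `sdi` (nucleus_id, stage, fun, model, sdi),
#'   `polarity`, `periphery`, `ks` (population tests), `failures`, `config`.
#' @export
run_spatial_analysis <- function(patterns, kinds = c("B", "C", "F", "G", "H"),
                                 models = list(random = null_model_spec("random"),
                                               orbital = null_model_spec("orbital")),
                                 cutoff_um = 0.5, n_sims = 99, seed = 1) {
  stopifnot(all(vapply(patterns, is_object_pattern, logical(1))))
  sdi_rows <- list(); pol_rows <- list(); per_rows <- list()
  failures <- list()
  for (i in seq_along(patterns)) {
    pat <- patterns[[i]]
    res <- tryCatch({
      srows <- list()
      for (mname in names(models)) {
        m <- models[[mname]]
        m$n_sims <- as.integer(n_sims)
        m$seed <- (seed * 1000L + i * length(models) +
                   match(mname, names(models))) %% .Machine$integer.max
        sdis <- compute_sdi(pat, kind = kinds, model = m)
        if (length(kinds) == 1L) sdis <- setNames(list(sdis), kinds)
        for (k in kinds)
          srows[[paste(mname, k)]] <- data.frame(
            nucleus_id = i, stage = pat$stage, fun = k, model = mname,
            sdi = sdis[[k]]$sdi)
      }
      pol <- lapply(c("major", "intermediate", "minor"), function(ax)
        data.frame(nucleus_id = i, stage = pat$stage, axis = ax,
                   index = polarity_index(pat, ax)$index))
      pf <- peripheral_fraction(pat, cutoff_um, method = "edt")
      list(s = do.call(rbind, srows), p = do.call(rbind, pol),
           f = data.frame(nucleus_id = i, stage = pat$stage,
                          cutoff_um = cutoff_um,
                          n_peripheral = pf$n_peripheral,
                          n_internal = pf$n_internal,
                          fraction_peripheral = pf$fraction_peripheral))
    }, error = function(e) e)
    if (inherits(res, "error")) {
      failures[[length(failures) + 1L]] <-
        data.frame(nucleus_id = i, message = conditionMessage(res))
      next
    }
    sdi_rows[[i]] <- res$s; pol_rows[[i]] <- res$p; per_rows[[i]] <- res$f
  }
  sdi <- do.call(rbind, sdi_rows)
  ks_rows <- list()
  if (!is.null(sdi)) {
    for (grp in split(sdi, list(sdi$stage, sdi$fun, sdi$model), drop = TRUE)) {
      ok <- nrow(grp) >= 5
      kt <- if (ok) population_uniformity_test(grp$sdi) else NULL
      ks_rows[[length(ks_rows) + 1L]] <- data.frame(
        stage = grp$stage[1], fun = grp$fun[1], model = grp$model[1],
        n = nrow(grp),
        ks_statistic = if (ok) kt$ks_statistic else NA_real_,
        p_value = if (ok) kt$p_value else NA_real_,
        note = if (ok) "" else "insufficient n")
    }
  }
  structure(list(sdi = sdi, polarity = do.call(rbind, pol_rows),
                 periphery = do.call(rbind, per_rows),
                 ks = do.call(rbind, ks_rows),
                 failures = do.call(rbind, failures),
                 config = list(kinds = kinds, models = names(models),
                               cutoff_um = cutoff_um, n_sims = n_sims,
                               seed = seed, n_nuclei = length(patterns))),
            class = "spatial_bundle")
}

#' @export
print.spatial_bundle <- function(x, ...) {
  n <- x$config$n_nuclei
  cat(sprintf("<spatial_bundle> %d nuclei, %d SDI rows, %d failure(s)\n",
              n, if (is.null(x$sdi)) 0L else nrow(x$sdi),
              if (is.null(x$failures)) 0L else nrow(x$failures)))
  invisible(x)
}

#' Write a human-readable report and machine-readable tables for a run
#'
#' @param bundle A [run_spatial_analysis()] result.
#' @param dir Output directory (created if needed).
#' @return Invisibly, the paths written.
#' @export
write_report <- function(bundle, dir) {
  stopifnot(inherits(bundle, "spatial_bundle"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  paths <- character(0)
  wr <- function(df, name) {
    if (is.null(df)) return(invisible(NULL))
    p <- file.path(dir, name)
    utils::write.csv(df, p, row.names = FALSE)
    paths <<- c(paths, p)
  }
  wr(bundle$sdi, "sdi.csv")
  wr(bundle$polarity, "polarity.csv")
  wr(bundle$periphery, "periphery.csv")
  wr(bundle$ks, "population_tests.csv")
  wr(bundle$failures, "failures.csv")
  prov <- file.path(dir, "provenance.json")
  jsonlite::write_json(c(bundle$config,
                         list(package = "nucleospat",
                              version = as.character(
                                utils::packageVersion("nucleospat")))),
                       prov, auto_unbox = TRUE)
  paths <- c(paths, prov)

  txt <- file.path(dir, "report.txt")
  con <- file(txt, "w")
  on.exit(close(con))
  if (bundle$config$n_nuclei == 0 || is.null(bundle$sdi)) {
    writeLines("no nuclei analyzed", con)
  } else {
    writeLines(sprintf("nuclei analyzed: %d (of %d submitted)",
                       length(unique(bundle$sdi$nucleus_id)),
                       bundle$config$n_nuclei), con)
    for (st in unique(bundle$periphery$stage)) {
      g <- bundle$periphery[bundle$periphery$stage == st, ]
      writeLines(sprintf(
        "stage %s: median peripheral fraction %.2f at %.2f um (n = %d)",
        st, stats::median(g$fraction_peripheral), g$cutoff_um[1], nrow(g)),
        con)
    }
    if (!is.null(bundle$ks)) {
      writeLines("population uniformity tests:", con)
      utils::write.table(format(bundle$ks, digits = 4), con, quote = FALSE,
                         row.names = FALSE)
    }
  }
  paths <- c(paths, txt)
  invisible(paths)
}
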