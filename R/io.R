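#' Write a clamp record to CSV
#'
#' Plain CSV with a commented metadata header block (lines starting with
#' `#`, `key: value`) followed by the column schema
#' time_min, glucose_mg_dl, tracer_dpm_ml, insulin_uU_ml, ginf_mg_kg_min,
#' fstar_dpm_kg_min. Portable and diff-able; numbers are written at full
#' precision so a write/read round trip is lossless.
#'
#' @param record a [clamp_record()].
#' @param path output file path.
#' @export
write_clamp_csv <- function(record, path) {
  stopifnot(inherits(record, "clamp_record"))
  meta <- c(id = record$id, diet = record$diet, state = record$state,
            weight_kg = format(record$weight, digits = 17),
            insulin_rate_mU_kg_min = format(record$insulin_rate, digits = 17),
            insulin_start_min = format(record$insulin_start, digits = 17),
            sa_inf_dpm_mg = format(record$SA_inf, digits = 17),
            tracer_units = "dpm")
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste0("# ", names(meta), ": ", meta), con)
  df <- data.frame(time_min = record$time, glucose_mg_dl = record$G,
                   tracer_dpm_ml = record$Gstar, insulin_uU_ml = record$I,
                   ginf_mg_kg_min = record$GINF,
                   fstar_dpm_kg_min = record$Fstar)
  writeLines(paste(names(df), collapse = ","), con)
  writeLines(do.call(paste, c(lapply(df, format, digits = 17),
                              list(sep = ","))), con)
  invisible(path)
}

.CLAMP_COLUMNS <- c("time_min", "glucose_mg_dl", "tracer_dpm_ml",
                    "insulin_uU_ml", "ginf_mg_kg_min", "fstar_dpm_kg_min")

#' Read a clamp record from CSV
#'
#' Parses the commented metadata header and the documented column schema,
#' validates it (named error for a missing column, first offending row for
#' unsorted time, offending rows for non-positive glucose) and converts
#' tracer columns from uCi to dpm when the header declares
#' `tracer_units: uCi`.
#'
#' @param path CSV written by [write_clamp_csv()] or following its schema.
#' @return a validated [clamp_record()].
#' @export
read_clamp_csv <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  lines <- readLines(path)
  meta_lines <- grep("^#", lines, value = TRUE)
  meta <- list()
  for (ln in meta_lines) {
    kv <- sub("^#\\s*", "", ln)
    key <- sub(":.*$", "", kv)
    val <- trimws(sub("^[^:]*:", "", kv))
    meta[[key]] <- val
  }
  need_meta <- c("weight_kg", "insulin_rate_mU_kg_min", "insulin_start_min",
                 "sa_inf_dpm_mg")
  miss <- setdiff(need_meta, names(meta))
  if (length(miss)) stop("missing metadata: ", paste(miss, collapse = ", "))
  df <- utils::read.csv(text = lines[!grepl("^#", lines)])
  missing_cols <- setdiff(.CLAMP_COLUMNS, names(df))
  if (length(missing_cols)) {
    stop("missing column: ", paste(missing_cols, collapse = ", "))
  }
  if (any(diff(df$time_min) <= 0)) {
    bad <- which(diff(df$time_min) <= 0)[1L] + 1L
    stop("unsorted input: time not strictly increasing at row ", bad)
  }
  tracer_scale <- 1
  if (identical(meta$tracer_units, "uCi")) tracer_scale <- DPM_PER_UCI
  sa_inf <- as.numeric(meta$sa_inf_dpm_mg)
  if (!is.null(meta$sa_inf_units) && identical(meta$sa_inf_units, "uCi_per_g")) {
    sa_inf <- sa_inf * DPM_PER_UCI / 1000
  }
  clamp_record(
    time = df$time_min, G = df$glucose_mg_dl,
    Gstar = df$tracer_dpm_ml * tracer_scale,
    I = df$insulin_uU_ml, GINF = df$ginf_mg_kg_min,
    Fstar = df$fstar_dpm_kg_min * tracer_scale,
    SA_inf = sa_inf,
    weight = as.numeric(meta$weight_kg),
    insulin_rate = as.numeric(meta$insulin_rate_mU_kg_min),
    insulin_start = as.numeric(meta$insulin_start_min),
    diet = if (!is.null(meta$diet)) meta$diet else "lean",
    state = if (!is.null(meta$state)) meta$state else "conscious",
    id = if (!is.null(meta$id)) meta$id else basename(path))
}

#' Run the full clamp analysis pipeline
#'
#' Simulate (or load) a cohort, smooth and compute tracer fluxes per
#' animal, derive sensitivity indices, summarize groups, run the two-way
#' ANOVA per endpoint, and write all artifacts to `outdir`: per-animal
#' flux CSVs, the per-animal sensitivity CSV, group summary CSV, ANOVA
#' report (JSON) and a run manifest recording the seed and configuration.
#' Idempotent given the seed.
#'
#' @param records list of [clamp_record()]s, or NULL to simulate.
#' @param n_per_group,conditions,dispersion,seed passed to
#'   [generate_cohort()] when `records` is NULL.
#' @param constants [kinetic_constants()] for the Steele analysis.
#' @param basal_window,ss_window averaging windows, min.
#' @param smooth_control smoother settings, see [compute_fluxes()].
#' @param anova_endpoints endpoints for the group comparison.
#' @param outdir output directory (created); NULL to skip writing.
#' @return invisibly, list with `sensitivity` (per-animal data.frame),
#'   `groups`, `anova` (per endpoint), `reductions`, `manifest`.
#' @export
run_pipeline <- function(records = NULL, n_per_group = c(16L, 16L, 16L, 8L),
                         conditions = names(clamp_presets()),
                         dispersion = 0.2, seed = 1L,
                         constants = kinetic_constants(),
                         basal_window = 30, ss_window = 30,
                         smooth_control = list(),
                         anova_endpoints = c("Rd_SS", "EGP_SS", "SI_P",
                                             "SI_H", "MCR"),
                         outdir = NULL) {
  sims <- NULL
  if (is.null(records)) {
    sims <- generate_cohort(n_per_group, conditions, dispersion, seed)
    records <- lapply(sims, `[[`, "record")
  }
  flux_list <- list()
  sens <- do.call(rbind, lapply(seq_along(records), function(i) {
    rec <- records[[i]]
    series <- compute_fluxes(rec, constants, smooth_control)
    flux_list[[i]] <<- series
    basal <- basal_flux(series, rec, basal_window)
    ss <- steady_state_summary(series, rec, ss_window)
    s <- compute_sensitivity(ss, basal, rec$insulin_rate)
    data.frame(id = rec$id, diet = rec$diet, state = rec$state,
               weight = rec$weight, insulin_rate = rec$insulin_rate,
               G_basal = s$G_basal, I_basal = s$I_basal,
               Rd_basal = s$Rd_basal, EGP_basal = s$EGP_basal,
               Gluc_SS = s$Gluc_SS, Ins_SS = s$Ins_SS,
               Rd_SS = s$Rd_SS, EGP_SS = s$EGP_SS,
               dRd = s$dRd, dEGP = s$dEGP, dIns = s$dIns,
               SI_P = s$SI_P, SI_H = s$SI_H, MCR = s$MCR,
               stringsAsFactors = FALSE)
  }))
  groups <- summarize_groups(sens)
  anovas <- list()
  if (length(unique(sens$diet)) >= 2L && length(unique(sens$state)) >= 2L) {
    for (ep in intersect(anova_endpoints, names(sens))) {
      anovas[[ep]] <- two_way_anova(sens[[ep]], sens$diet, sens$state)
    }
  }
  reductions <- if (length(unique(sens$state)) >= 2L) {
    anesthesia_reductions(sens)
  } else NULL
  manifest <- list(seed = seed, n_animals = nrow(sens),
                   constants = constants,
                   basal_window = basal_window, ss_window = ss_window,
                   smooth_control = smooth_control,
                   package_version = as.character(utils::packageVersion("clampkin")),
                   timestamp_free = TRUE)
  if (!is.null(outdir)) {
    dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
    for (i in seq_along(records)) {
      utils::write.csv(as.data.frame(flux_list[[i]]),
                       file.path(outdir, paste0("flux_", records[[i]]$id, ".csv")),
                       row.names = FALSE)
    }
    utils::write.csv(sens, file.path(outdir, "sensitivity.csv"), row.names = FALSE)
    utils::write.csv(groups, file.path(outdir, "group_summary.csv"), row.names = FALSE)
    if (length(anovas)) {
      jsonlite::write_json(lapply(anovas, function(a) a$table),
                           file.path(outdir, "anova_report.json"),
                           auto_unbox = TRUE, digits = NA)
    }
    if (!is.null(reductions)) {
      utils::write.csv(reductions, file.path(outdir, "reductions.csv"),
                       row.names = FALSE)
    }
    jsonlite::write_json(manifest, file.path(outdir, "manifest.json"),
                         auto_unbox = TRUE, digits = NA)
  }
  invisible(list(sensitivity = sens, groups = groups, anova = anovas,
                 reductions = reductions, manifest = manifest, sims = sims))
}
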