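# Pipeline orchestration: simulate -> measure -> stats, each stage writing
# tidy CSVs plus a manifest, reproducible from the configuration and seeds.

log_line <- function(log_path, ...) {
  msg <- paste0(format(Sys.time(), "%H:%M:%S"), " ", paste0(...))
  message(msg)
  if (!is.null(log_path)) cat(msg, "\n", file = log_path, append = TRUE)
}

write_manifest <- function(dir, files) {
  files <- files[file.exists(file.path(dir, files))]
  manifest <- data.frame(file = files,
                         md5 = unname(tools::md5sum(file.path(dir, files))),
                         stringsAsFactors = FALSE)
  jsonlite::write_json(manifest, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA)
  manifest
}

#' Simulate a factorial imaging experiment to disk
#'
#' Renders every field of the design as a multi-page TIFF with sidecar,
#' and writes `design.csv` (field_id, replicate, katp_level, rotenone),
#' `truth.csv` (per-field true metric values), `truth_means.csv`
#' (condition means), `mtt.csv`, `counts.csv` and a `manifest.json` with
#' file hashes.
#'
#' @param spec an [effect_spec()]; its `seed` drives all randomness.
#' @param out_dir output directory (created).
#' @param rspec a [render_spec()].
#' @param image_shape rendered field size.
#' @param n_branches branches per rendered network.
#' @return the experiment object, invisibly.
#' @export
mn_simulate <- function(spec = effect_spec(), out_dir,
                        rspec = render_spec(), image_shape = c(256, 256),
                        n_branches = 12) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  log_path <- file.path(out_dir, "run.log")
  log_line(log_path, "simulate: ", length(spec$factor_a_levels), "x",
           length(spec$factor_b_levels), " design, ", spec$n_replicates,
           " replicates, ", spec$fields_per_replicate, " fields each")
  exp <- generate_experiment(spec, render = TRUE, rspec = rspec,
                             image_shape = image_shape,
                             n_branches = n_branches, out_dir = out_dir)
  design <- exp$fields[c("field_id", "replicate", "katp_level", "rotenone")]
  write.csv(design, file.path(out_dir, "design.csv"), row.names = FALSE)
  write.csv(exp$fields, file.path(out_dir, "truth.csv"), row.names = FALSE)
  write.csv(exp$truth, file.path(out_dir, "truth_means.csv"),
            row.names = FALSE)
  write.csv(exp$mtt, file.path(out_dir, "mtt.csv"), row.names = FALSE)
  write.csv(exp$counts, file.path(out_dir, "counts.csv"), row.names = FALSE)
  files <- c("design.csv", "truth.csv", "truth_means.csv", "mtt.csv",
             "counts.csv", paste0(design$field_id, ".tif"),
             paste0(design$field_id, ".tif.json"))
  write_manifest(out_dir, files)
  log_line(log_path, "simulate: wrote ", nrow(design), " fields to ",
           out_dir)
  invisible(exp)
}

#' Measure all fields of a simulated or imported dataset
#'
#' Reads `design.csv` from `in_dir`, measures every field
#' ([measure_field()], [measure_calcium()]) and writes tidy
#' `morphology.csv` and `calcium.csv` to `out_dir`. Unreadable images
#' yield flagged rows, never abort the run; the number of failures is
#' returned and logged.
#'
#' @param in_dir dataset directory.
#' @param out_dir output directory (default: `in_dir`).
#' @param config an [mn_config()].
#' @return list with `morphology` and `calcium` data.frames and `n_failed`.
#' @export
mn_measure <- function(in_dir, out_dir = in_dir, config = mn_config()) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  log_path <- file.path(out_dir, "run.log")
  design <- read.csv(file.path(in_dir, "design.csv"),
                     stringsAsFactors = FALSE)
  morph <- NULL; calc <- NULL; n_failed <- 0L
  for (i in seq_len(nrow(design))) {
    d <- design[i, ]
    t0 <- Sys.time()
    res <- tryCatch({
      f <- read_field(file.path(in_dir, paste0(d$field_id, ".tif")))
      list(m = measure_field(f, config), c = measure_calcium(f, config))
    }, error = function(e) e)
    if (inherits(res, "error")) {
      n_failed <- n_failed + 1L
      log_line(log_path, "measure FAILED ", d$field_id, ": ",
               conditionMessage(res))
      flagrow <- data.frame(field_id = d$field_id, replicate = d$replicate,
                            katp_level = d$katp_level,
                            rotenone = d$rotenone,
                            qc_flag = "read_error",
                            stringsAsFactors = FALSE)
      morph <- merge_rows(morph, flagrow)
      calc <- merge_rows(calc, flagrow)
    } else {
      morph <- merge_rows(morph, res$m)
      calc <- merge_rows(calc, res$c)
      log_line(log_path, "measure ", d$field_id, " ok (",
               round(as.numeric(Sys.time() - t0, units = "secs"), 2), "s)",
               if (nzchar(res$m$qc_flag)) paste0(" flag=", res$m$qc_flag))
    }
  }
  write.csv(morph, file.path(out_dir, "morphology.csv"), row.names = FALSE)
  write.csv(calc, file.path(out_dir, "calcium.csv"), row.names = FALSE)
  invisible(list(morphology = morph, calcium = calc, n_failed = n_failed))
}

merge_rows <- function(df, row) {
  if (is.null(df)) return(row)
  for (nm in setdiff(names(df), names(row))) row[[nm]] <- NA
  for (nm in setdiff(names(row), names(df))) df[[nm]] <- NA
  rbind(df, row[names(df)])
}

#' Run the inference layer over measured (or simulated) tables
#'
#' Joins morphology, calcium and viability tables on (replicate,
#' katp_level, rotenone) at the replicate level, then for every variable
#' runs the balanced two-way ANOVA with gatekept Tukey comparisons,
#' t-tests of each treated condition against the control cell, and one
#' pooled Pearson correlation matrix across variables.
#'
#' @param replicate_df replicate-level `data.frame` (see
#'   [aggregate_replicates()], [viability_table()]) with condition columns
#'   and numeric variables.
#' @param alpha significance level.
#' @param control_katp,control_rotenone labels of the reference cell for
#'   the t-tests.
#' @return list of class `mn_stats_report`: per-variable `anova`
#'   tables and `posthoc` results, `ttests`, `correlations`, `alpha`.
#' @export
analyze_experiment <- function(replicate_df, alpha = 0.05,
                               control_katp = "ctrl",
                               control_rotenone = "vehicle") {
  need <- c("replicate", "katp_level", "rotenone")
  stopifnot(all(need %in% names(replicate_df)))
  vars <- setdiff(names(replicate_df)[vapply(replicate_df, is.numeric,
                                             TRUE)], need)
  cells <- table(replicate_df$katp_level, replicate_df$rotenone)
  if (any(cells == 0)) {
    miss <- which(cells == 0, arr.ind = TRUE)
    stop("missing design cells: ",
         paste(rownames(cells)[miss[, 1]], colnames(cells)[miss[, 2]],
               sep = "/", collapse = ", "))
  }
  anovas <- list(); posthocs <- list()
  ttests <- NULL
  ctrl_sel <- replicate_df$katp_level == control_katp &
    replicate_df$rotenone == control_rotenone
  for (v in vars) {
    y <- replicate_df[[v]]
    ok <- is.finite(y)
    if (!all(ok)) next
    tab <- two_way_anova(y, replicate_df$katp_level,
                         replicate_df$rotenone,
                         term_names = c("katp", "rotenone"))
    anovas[[v]] <- tab
    posthocs[[v]] <- gatekept_posthoc(tab, alpha = alpha)
    # direct comparisons of each treated cell to control cells
    for (a in unique(replicate_df$katp_level)) {
      for (b in unique(replicate_df$rotenone)) {
        if (a == control_katp && b == control_rotenone) next
        sel <- replicate_df$katp_level == a & replicate_df$rotenone == b
        tt <- students_t(y[sel], y[ctrl_sel])
        ttests <- rbind(ttests, data.frame(
          variable = v, katp_level = a, rotenone = b, t = tt$t,
          df = tt$df, p_value = tt$p_value, flag = tt$flag,
          stringsAsFactors = FALSE))
      }
    }
  }
  cors <- pearson_matrix(replicate_df[vars])
  structure(list(anova = anovas, posthoc = posthocs, ttests = ttests,
                 correlations = cors, alpha = alpha, variables = vars),
            class = "mn_stats_report")
}

#' @export
print.mn_stats_report <- function(x, ...) {
  cat("stats report:", length(x$anova), "variables, alpha =", x$alpha, "\n")
  for (v in names(x$anova)) {
    p <- x$anova[[v]]$p_value[1:3]
    cat(sprintf("  %-22s p(katp)=%.4g p(rotenone)=%.4g p(interaction)=%.4g\n",
                v, p[1], p[2], p[3]))
  }
  invisible(x)
}

#' Stats stage over a measured dataset directory
#'
#' Reads `morphology.csv`, `calcium.csv`, `mtt.csv`, `counts.csv` from
#' `in_dir`, aggregates fields per biological replicate, joins all
#' variables and writes `anova.csv`, `tukey.csv`, `ttests.csv`,
#' `correlations.csv` and `report.json` (alpha, gatekeeping decisions) to
#' `out_dir`.
#'
#' @param in_dir directory with measured tables.
#' @param out_dir output directory (default: `in_dir`).
#' @param alpha significance level.
#' @return the `mn_stats_report`, invisibly.
#' @export
mn_stats <- function(in_dir, out_dir = in_dir, alpha = 0.05) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  log_path <- file.path(out_dir, "run.log")
  morph <- read.csv(file.path(in_dir, "morphology.csv"),
                    stringsAsFactors = FALSE)
  calc <- read.csv(file.path(in_dir, "calcium.csv"),
                   stringsAsFactors = FALSE)
  if (nrow(morph) == 0 || nrow(calc) == 0) {
    stop("empty metrics tables in ", in_dir)
  }
  keep_m <- aggregate_replicates(
    morph[c("replicate", "katp_level", "rotenone", "fragmentation",
            "branching", "mean_branch_length_um")])
  keep_c <- aggregate_replicates(
    calc[c("replicate", "katp_level", "rotenone", "ca_whole_cell",
           "ca_mito", "ca_er")])
  df <- merge(keep_m, keep_c, by = c("replicate", "katp_level", "rotenone"))
  mtt_path <- file.path(in_dir, "mtt.csv")
  cnt_path <- file.path(in_dir, "counts.csv")
  if (file.exists(mtt_path) && file.exists(cnt_path)) {
    viab <- viability_table(read.csv(mtt_path, stringsAsFactors = FALSE),
                            read.csv(cnt_path, stringsAsFactors = FALSE))
    df <- merge(df, viab, by = c("replicate", "katp_level", "rotenone"))
  }
  report <- analyze_experiment(df, alpha = alpha)

  an <- do.call(rbind, lapply(names(report$anova), function(v) {
    cbind(variable = v, as.data.frame(report$anova[[v]]))
  }))
  write.csv(an, file.path(out_dir, "anova.csv"), row.names = FALSE)
  tk <- do.call(rbind, lapply(names(report$posthoc), function(v) {
    ph <- report$posthoc[[v]]
    if (length(ph$comparisons) == 0) return(NULL)
    do.call(rbind, lapply(names(ph$comparisons), function(fam) {
      cbind(variable = v, family = fam,
            as.data.frame(ph$comparisons[[fam]]))
    }))
  }))
  if (is.null(tk)) {
    tk <- data.frame(variable = character(0), family = character(0))
  }
  write.csv(tk, file.path(out_dir, "tukey.csv"), row.names = FALSE)
  write.csv(report$ttests, file.path(out_dir, "ttests.csv"),
            row.names = FALSE)
  cor_df <- as.data.frame(report$correlations$r)
  cor_df <- cbind(variable = rownames(cor_df), cor_df)
  write.csv(cor_df, file.path(out_dir, "correlations.csv"),
            row.names = FALSE)
  gk <- lapply(report$posthoc, function(ph) {
    list(interaction_significant = ph$interaction_significant,
         families = names(ph$comparisons), note = ph$note)
  })
  jsonlite::write_json(list(alpha = alpha, gatekeeping = gk,
                            variables = report$variables),
                       file.path(out_dir, "report.json"),
                       auto_unbox = TRUE, digits = NA)
  log_line(log_path, "stats: ", length(report$anova),
           " variables analysed at alpha=", alpha)
  invisible(report)
}
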