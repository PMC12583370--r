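# Factorial experiment simulation: per-variable hierarchical draws
# (condition cell mean -> biological replicate -> field) matching the
# design of the imaging study (KATP modulation x rotenone), plus MTT-well
# and cell-count tables.

default_variables <- function() {
  v <- function(baseline, between_sd, within_sd) {
    list(baseline = baseline, between_sd = between_sd, within_sd = within_sd)
  }
  list(
    fragmentation         = v(0.25, 0.04, 0.06),
    branching             = v(0.33, 0.03, 0.05),
    mean_branch_length_um = v(2.0, 0.20, 0.30),
    ca_whole_cell         = v(40, 4, 6),
    ca_mito               = v(100, 10, 15),
    ca_er                 = v(60, 6, 9),
    mtt_percent           = v(100, 8, 10),
    cell_count            = v(120, 12, 15)
  )
}

#' Factorial effect specification for simulated experiments
#'
#' Defines a complete 2-factor design (KATP treatment x rotenone) and, per
#' measured variable, a baseline cell mean, a between-replicate sd, a
#' within-replicate (field-to-field) sd, and optional per-level mean
#' shifts. Defaults emulate the imaging design: 5 biological replicates
#' per condition, 5 fields per replicate, three KATP levels
#' (ctrl/agonist/antagonist) crossed with vehicle/rotenone, and all shifts
#' zero (the global null).
#'
#' @param factor_a_levels KATP treatment labels.
#' @param factor_b_levels second factor labels (vehicle first).
#' @param n_replicates biological replicates per condition (>= 2).
#' @param fields_per_replicate imaged fields (and count images) per
#'   replicate (>= 1).
#' @param wells_per_replicate MTT wells per replicate.
#' @param variables named list as produced by the internal defaults; each
#'   entry holds `baseline`, `between_sd`, `within_sd`.
#' @param shifts named list (by variable) of lists with numeric vectors
#'   `a` (named by `factor_a_levels`) and/or `b` (named by
#'   `factor_b_levels`) of additive mean shifts.
#' @param seed integer seed.
#' @return list of class `effect_spec`.
#' @export
effect_spec <- function(factor_a_levels = c("ctrl", "agonist", "antagonist"),
                        factor_b_levels = c("vehicle", "rotenone"),
                        n_replicates = 5, fields_per_replicate = 5,
                        wells_per_replicate = 3,
                        variables = default_variables(),
                        shifts = NULL, seed = NULL) {
  stopifnot(n_replicates >= 2, fields_per_replicate >= 1,
            wells_per_replicate >= 1,
            length(factor_a_levels) >= 2, length(factor_b_levels) >= 2)
  for (v in variables) {
    stopifnot(v$between_sd >= 0, v$within_sd >= 0)
  }
  structure(list(factor_a_levels = factor_a_levels,
                 factor_b_levels = factor_b_levels,
                 n_replicates = n_replicates,
                 fields_per_replicate = fields_per_replicate,
                 wells_per_replicate = wells_per_replicate,
                 variables = variables,
                 shifts = shifts %||% list(),
                 seed = seed),
            class = "effect_spec")
}

#' Apply the reported effect directions to an effect specification
#'
#' Sets additive mean shifts mirroring the directions reported for this
#' system: rotenone increases fragmentation and decreases branching,
#' calcium in all compartments, MTT turnover and cell counts; KATP
#' modulators (all non-control levels) increase mean branch length and
#' cell counts. Shift magnitudes are expressed in units of each variable's
#' between-replicate sd.
#'
#' @param spec an [effect_spec()].
#' @param magnitude shift size in between-replicate sds.
#' @return the modified `effect_spec`.
#' @export
reported_effects <- function(spec, magnitude = 2) {
  stopifnot(inherits(spec, "effect_spec"))
  bl <- spec$factor_b_levels[2]
  mods <- setdiff(spec$factor_a_levels, spec$factor_a_levels[1])
  sh <- function(var, dir_b = 0, dir_a = 0) {
    s <- list()
    bsd <- spec$variables[[var]]$between_sd
    if (dir_b != 0) s$b <- setNames(dir_b * magnitude * bsd, bl)
    if (dir_a != 0) s$a <- setNames(rep(dir_a * magnitude * bsd,
                                        length(mods)), mods)
    s
  }
  spec$shifts <- list(
    fragmentation = sh("fragmentation", dir_b = +1),
    branching = sh("branching", dir_b = -1),
    mean_branch_length_um = sh("mean_branch_length_um", dir_a = +1),
    ca_whole_cell = sh("ca_whole_cell", dir_b = -1),
    ca_mito = sh("ca_mito", dir_b = -1),
    ca_er = sh("ca_er", dir_b = -1),
    mtt_percent = sh("mtt_percent", dir_b = -1),
    cell_count = sh("cell_count", dir_b = -1, dir_a = +1)
  )
  spec
}

cell_mean <- function(spec, var, a_level, b_level) {
  v <- spec$variables[[var]]
  s <- spec$shifts[[var]]
  mu <- v$baseline
  if (!is.null(s$a) && a_level %in% names(s$a)) mu <- mu + s$a[[a_level]]
  if (!is.null(s$b) && b_level %in% names(s$b)) mu <- mu + s$b[[b_level]]
  if (!is.null(s$ab)) mu <- mu + (s$ab[a_level, b_level] %||% 0)
  mu
}

#' Simulate a full factorial experiment
#'
#' For every condition cell and biological replicate, latent replicate
#' means are drawn around the condition mean with the between-replicate
#' sd; per-field values are drawn around the replicate mean with the
#' within-replicate sd. Morphology and calcium variables are tabulated per
#' field; MTT absorbances per well (scaled so the control-condition mean
#' percentage is 100 after normalization) and cell counts per image are
#' tabulated for the viability layer. The generating truth (all condition
#' means) is returned alongside.
#'
#' With `render = TRUE`, each field is additionally realized as a
#' three-channel image: the field's morphology draws are quantized to the
#' nearest feasible network topology (which then defines the field's true
#' metric values), and its calcium draws become the rendered compartment
#' levels above background.
#'
#' @param spec an [effect_spec()].
#' @param render render fields as images (slow; in-memory unless
#'   `out_dir` given).
#' @param rspec a [render_spec()] used when rendering.
#' @param image_shape rendered field size.
#' @param n_branches total branch count per rendered field.
#' @param out_dir when rendering, write fields/truth/design here (see
#'   [write_field()]).
#' @return list of class `mn_experiment`: `fields` (per-field tidy
#'   `data.frame`), `mtt`, `counts`, `truth` (condition-mean table),
#'   `spec`, and (when rendered in memory) `images`.
#' @export
generate_experiment <- function(spec = effect_spec(), render = FALSE,
                                rspec = render_spec(),
                                image_shape = c(256, 256),
                                n_branches = 12, out_dir = NULL) {
  stopifnot(inherits(spec, "effect_spec"))
  with_seed(spec$seed, {
    al <- spec$factor_a_levels; bl <- spec$factor_b_levels
    vars <- names(spec$variables)
    field_vars <- setdiff(vars, c("mtt_percent", "cell_count"))
    fields <- NULL; mtt <- NULL; counts <- NULL
    truth <- NULL
    images <- list()
    fid <- 0L
    for (a in al) for (b in bl) {
      for (v in vars) {
        truth <- rbind(truth, data.frame(
          variable = v, katp_level = a, rotenone = b,
          true_mean = cell_mean(spec, v, a, b), stringsAsFactors = FALSE))
      }
      for (r in seq_len(spec$n_replicates)) {
        rep_id <- sprintf("R%d", r)
        rep_means <- vapply(vars, function(v) {
          rnorm(1, cell_mean(spec, v, a, b), spec$variables[[v]]$between_sd)
        }, 0)
        # morphology + calcium: one value per field
        for (f in seq_len(spec$fields_per_replicate)) {
          fid <- fid + 1L
          vals <- vapply(field_vars, function(v) {
            rnorm(1, rep_means[[v]], spec$variables[[v]]$within_sd)
          }, 0)
          vals["fragmentation"] <- min(max(vals["fragmentation"], 0), 1)
          vals["branching"] <- max(vals["branching"], 0)
          vals["mean_branch_length_um"] <- max(vals["mean_branch_length_um"],
                                               0.1)
          vals[c("ca_whole_cell", "ca_mito", "ca_er")] <-
            pmax(vals[c("ca_whole_cell", "ca_mito", "ca_er")], 0)
          row <- data.frame(field_id = sprintf("F%05d", fid),
                            replicate = rep_id, katp_level = a,
                            rotenone = b, t(vals),
                            stringsAsFactors = FALSE)
          if (render) {
            rf <- render_experiment_field(row, rspec, image_shape,
                                          n_branches)
            # realized (quantized) truth replaces the latent draws
            row$fragmentation <- rf$realized["fragmentation"]
            row$branching <- rf$realized["branching"]
            row$mean_branch_length_um <- rf$realized["mean_branch_length_um"]
            if (is.null(out_dir)) {
              images[[row$field_id]] <- rf$field
            } else {
              write_field(rf$field, file.path(out_dir,
                                              paste0(row$field_id, ".tif")))
            }
          }
          fields <- rbind(fields, row)
        }
        # MTT wells: absorbance scaled to a 0.6 AU control mean
        pct <- rnorm(spec$wells_per_replicate, rep_means[["mtt_percent"]],
                     spec$variables[["mtt_percent"]]$within_sd)
        mtt <- rbind(mtt, data.frame(
          replicate = rep_id, katp_level = a, rotenone = b,
          well = seq_len(spec$wells_per_replicate),
          absorbance = pmax(pct, 0) / 100 * 0.6, stringsAsFactors = FALSE))
        # cell counts per image
        cnt <- pmax(round(rnorm(spec$fields_per_replicate,
                                rep_means[["cell_count"]],
                                spec$variables[["cell_count"]]$within_sd)), 0)
        counts <- rbind(counts, data.frame(
          replicate = rep_id, katp_level = a, rotenone = b,
          image = seq_len(spec$fields_per_replicate), count = cnt,
          stringsAsFactors = FALSE))
      }
    }
    out <- list(fields = fields, mtt = mtt, counts = counts, truth = truth,
                spec = spec)
    if (render && is.null(out_dir)) out$images <- images
    class(out) <- "mn_experiment"
    out
  })
}

# map latent (fragmentation, branching, length) draws to the nearest
# feasible network topology and render it
render_experiment_field <- function(row, rspec, image_shape, n_branches) {
  B <- n_branches
  J <- round(row$branching * B)
  J <- max(0L, min(J, floor((B - 1) / 2)))
  if (J == 0) {
    R <- B
  } else {
    m <- B - round(row$fragmentation * B)
    m <- max(2 * J + 1, min(m, min(4 * J, B)))
    R <- B - m
  }
  len_px <- max(row$mean_branch_length_um / rspec$pixel_size, 12)
  lr <- c(max(15, 0.6 * len_px), max(21, 1.4 * len_px))
  net <- generate_network(B, J, R, length_range = lr,
                          image_shape = image_shape,
                          min_spacing = ceiling(2 * rspec$tube_radius +
                                                  3 * rspec$psf_sigma) + 2)
  ca <- calcium_levels(
    whole_cell = rspec$background_level + row$ca_whole_cell,
    mito = rspec$background_level + row$ca_mito,
    er = rspec$background_level + row$ca_er)
  f <- render_field(net, calcium = ca, spec = rspec,
                    katp_level = row$katp_level, rotenone = row$rotenone,
                    replicate_id = row$replicate, field_id = row$field_id)
  g <- build_graph(net$skeleton)
  list(field = f,
       realized = c(
         fragmentation = g$rod_count / g$branch_count,
         branching = g$junction_count / g$branch_count,
         mean_branch_length_um = mean(g$branch_lengths_px) *
           rspec$pixel_size))
}

#' Aggregate per-field measurements to biological replicates
#'
#' Averages all numeric measurement columns over fields within each
#' (replicate, condition) cell — the analysis unit of the inference layer,
#' avoiding pseudo-replication from multiple fields per replicate.
#'
#' @param fields_df per-field `data.frame` with `replicate`, `katp_level`,
#'   `rotenone` and numeric measurement columns.
#' @return replicate-level `data.frame`.
#' @export
aggregate_replicates <- function(fields_df) {
  stopifnot(all(c("replicate", "katp_level", "rotenone") %in%
                  names(fields_df)))
  num <- names(fields_df)[vapply(fields_df, is.numeric, TRUE)]
  aggregate(fields_df[num],
            fields_df[c("replicate", "katp_level", "rotenone")],
            mean, na.rm = TRUE)
}
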