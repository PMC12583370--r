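#' Build a typed graph from a 1-pixel-wide skeleton
#'
#' Skeleton pixels are classified by their 8-connected neighbour count:
#' 0-1 neighbours = endpoint (or isolated pixel), 2 = branch interior,
#' >= 3 = junction. Adjacent junction pixels are merged into one junction
#' node (thinning often leaves small junction clusters). Branches are the
#' 8-connected components of the non-junction pixels; each branch records
#' the junction nodes it terminates at. A connected component of the
#' skeleton containing no junction pixel is a solitary rod; closed loops
#' are branches whose two terminals coincide (or rods, when junction-free).
#'
#' @param skeleton logical matrix, 1 pixel wide (see [skeletonize()]).
#' @param junction_merge_px when > 0, junction nodes connected by an
#'   internal branch of at most this many path pixels are merged into one
#'   node and the bridge absorbed; use about the tube diameter to undo
#'   junction splitting introduced by thinning thick junction blobs. 0
#'   (default) leaves the graph untouched.
#' @return object of class `skeleton_graph`: a list with `branch_count`,
#'   `junction_count`, `rod_count`, `branch_lengths_px` (pixel counts, each
#'   branch including one pixel per terminal junction node),
#'   `component_count`, `branches` (per-branch pixel coordinate matrices),
#'   `junctions` (per-node pixel coordinate matrices) and `qc_flags`.
#' @export
build_graph <- function(skeleton, junction_merge_px = 0) {
  stopifnot(is.matrix(skeleton), junction_merge_px >= 0)
  skel <- as_binary_int(skeleton)
  flags <- character(0)
  if (!any(skel == 1L)) {
    g <- list(branch_count = 0L, junction_count = 0L, rod_count = 0L,
              branch_lengths_px = numeric(0), component_count = 0L,
              branches = list(), junctions = list(),
              qc_flags = "empty_skeleton")
    class(g) <- "skeleton_graph"
    return(g)
  }
  deg <- nbr_count8(skel)
  junc <- skel == 1L & deg >= 3L
  comp <- label8(skel)
  jlab <- label8(as_binary_int(junc))
  bpx <- skel == 1L & !junc
  blab <- label8(as_binary_int(bpx))
  nJ <- max(jlab)
  nB <- max(blab)

  # branch <-> junction-node adjacency via junction pixels' neighbourhoods
  adj <- matrix(integer(0), 0, 2)  # (branch label, junction node)
  if (nJ > 0) {
    jc <- which(jlab > 0, arr.ind = TRUE)
    pairs <- vector("list", nrow(jc))
    nr <- nrow(skel); nc <- ncol(skel)
    for (i in seq_len(nrow(jc))) {
      r <- jc[i, 1]; c <- jc[i, 2]
      rr <- max(1, r - 1):min(nr, r + 1)
      cc <- max(1, c - 1):min(nc, c + 1)
      bl <- blab[rr, cc]
      bl <- unique(bl[bl > 0])
      if (length(bl)) pairs[[i]] <- cbind(bl, jlab[r, c])
    }
    adj <- unique(do.call(rbind, c(pairs, list(matrix(integer(0), 0, 2)))))
  }

  sizes <- tabulate(blab[blab > 0], nbins = nB)

  # optionally merge junction nodes bridged by very short internal branches
  # (thinning splits thick junction blobs into nearby clusters)
  jclass <- seq_len(max(nJ, 0L))
  keep <- rep(TRUE, nB)
  if (junction_merge_px > 0 && nJ > 1 && nB > 0 && nrow(adj) > 0) {
    find <- function(x) { while (jclass[x] != x) x <- jclass[x]; x }
    for (b in which(sizes <= junction_merge_px)) {
      cl <- unique(adj[adj[, 1] == b, 2])
      if (length(cl) == 2) {
        r1 <- find(cl[1]); r2 <- find(cl[2])
        if (r1 != r2) jclass[r2] <- r1
        keep[b] <- FALSE
      }
    }
    jclass <- vapply(seq_len(nJ), find, 0L)
  }
  nJ_eff <- if (nJ > 0) length(unique(jclass)) else 0L

  # pixel counts per branch; add one pixel per distinct terminal junction
  n_terminals <- integer(nB)
  if (nrow(adj) > 0) {
    cls <- jclass[adj[, 2]]
    for (b in seq_len(nB)) {
      n_terminals[b] <- length(unique(cls[adj[, 1] == b]))
    }
  }
  lengths_px <- (sizes + n_terminals)[keep]

  # rods: whole-skeleton components without junction pixels
  jcomp <- unique(comp[junc])
  all_comp <- seq_len(max(comp))
  rod_comps <- setdiff(all_comp, jcomp)
  rod_count <- length(rod_comps)

  # components made only of junction pixels contribute no branch (degenerate)
  if (nJ > 0 && any(!jcomp %in% unique(comp[bpx])) && nB < rod_count) {
    flags <- c(flags, "junction_only_component")
  }

  branches <- lapply(which(keep), function(b) which(blab == b, arr.ind = TRUE))
  junctions <- list()
  if (nJ > 0) {
    for (cl in unique(jclass)) {
      members <- which(jclass == cl)
      px <- which(matrix(jlab %in% members, nrow(jlab)), arr.ind = TRUE)
      absorbed <- which(!keep)[vapply(which(!keep), function(b) {
        all(jclass[unique(adj[adj[, 1] == b, 2])] == cl)
      }, TRUE)]
      if (length(absorbed)) {
        px <- rbind(px, which(matrix(blab %in% absorbed, nrow(blab)),
                              arr.ind = TRUE))
      }
      junctions[[length(junctions) + 1L]] <- px
    }
  }

  g <- list(branch_count = sum(keep), junction_count = nJ_eff,
            rod_count = rod_count,
            branch_lengths_px = as.numeric(lengths_px),
            component_count = max(comp),
            branches = branches, junctions = junctions,
            qc_flags = flags)
  class(g) <- "skeleton_graph"
  g
}

#' @export
print.skeleton_graph <- function(x, ...) {
  cat("skeleton graph:", x$branch_count, "branches,",
      x$junction_count, "junctions,", x$rod_count, "rods,",
      x$component_count, "components\n")
  invisible(x)
}

metric_or_na <- function(graph, f) {
  if (graph$branch_count == 0L) {
    warning("metric undefined: skeleton has no branches", call. = FALSE)
    return(NA_real_)
  }
  f(graph)
}

#' Mitochondrial fragmentation: solitary rods / total branches
#'
#' Ratio of solitary rod-shaped components (connected skeleton components
#' containing no junction) to the total number of branches. Every rod is
#' itself one branch, so the ratio lies in \[0, 1\].
#'
#' @param graph a `skeleton_graph`.
#' @return fragmentation ratio, or `NA` (with warning) when the skeleton
#'   has no branches.
#' @export
fragmentation <- function(graph) {
  stopifnot(inherits(graph, "skeleton_graph"))
  metric_or_na(graph, function(g) g$rod_count / g$branch_count)
}

#' Mitochondrial branching: junction nodes / total branches
#'
#' @param graph a `skeleton_graph`.
#' @return branching ratio (>= 0), or `NA` when no branches.
#' @export
branching <- function(graph) {
  stopifnot(inherits(graph, "skeleton_graph"))
  metric_or_na(graph, function(g) g$junction_count / g$branch_count)
}

#' Mean branch length
#'
#' Average over branches of the branch pixel count times the pixel size.
#' Each branch's count includes its terminal node pixels, a shared junction
#' node counting once per branch that ends there.
#'
#' @param graph a `skeleton_graph`.
#' @param pixel_size length of one pixel (e.g. micrometres/pixel); 1 gives
#'   lengths in pixels.
#' @return mean branch length, or `NA` when no branches.
#' @export
mean_branch_length <- function(graph, pixel_size = 1) {
  stopifnot(inherits(graph, "skeleton_graph"), pixel_size > 0)
  metric_or_na(graph, function(g) mean(g$branch_lengths_px) * pixel_size)
}

#' Extend skeleton tips to the end caps of their mask
#'
#' Iterative thinning stops a tube's centerline short of the tube end by
#' roughly the tube half-width. This walks each skeleton endpoint outward
#' along its local direction, while the mask's distance map stays at or
#' above the typical centerline half-width (the tube's medial radius), i.e.
#' up to the center of the rounded end cap. Corrects the systematic
#' under-estimation of branch length on tube-rendered structures.
#'
#' @param skeleton logical skeleton matrix.
#' @param mask logical mask the skeleton was thinned from.
#' @param tip_offset sub-pixel correction (px) added to the extension
#'   target, compensating the half-pixel offset between pixel-center
#'   distances and the geometric mask boundary.
#' @return logical skeleton matrix with extended tips.
#' @export
extend_skeleton_tips <- function(skeleton, mask, tip_offset = 0.25) {
  stopifnot(is.matrix(skeleton), identical(dim(skeleton), dim(mask)))
  if (!any(skeleton)) return(skeleton)
  dm <- EBImage::imageData(EBImage::distmap(EBImage::Image(mask * 1)))
  skel <- skeleton
  rhat <- median(dm[skel])
  deg <- nbr_count8(as_binary_int(skel))
  ends <- which(skel & deg == 1L, arr.ind = TRUE)
  nr <- nrow(skel); nc <- ncol(skel)
  for (i in seq_len(nrow(ends))) {
    p <- ends[i, ]
    # local direction from a few steps back along the branch
    path <- matrix(p, 1, 2)
    cur <- p
    prev <- NULL
    for (s in 1:4) {
      nb <- expand.grid(r = cur[1] + (-1):1, c = cur[2] + (-1):1)
      nb <- nb[nb$r >= 1 & nb$r <= nr & nb$c >= 1 & nb$c <= nc, ]
      nb <- nb[skel[cbind(nb$r, nb$c)], , drop = FALSE]
      nb <- nb[!(paste(nb$r, nb$c) %in% paste(path[, 1], path[, 2])), ,
               drop = FALSE]
      if (nrow(nb) != 1) break
      cur <- c(nb$r[1], nb$c[1])
      path <- rbind(path, cur)
    }
    if (nrow(path) < 2) next
    v <- p - path[nrow(path), ]
    v <- v / sqrt(sum(v^2))
    # arc distance from the tip to the mask boundary along the tip direction;
    # the true segment end (cap center) sits one medial radius short of it
    maxarc <- 2 * rhat + 4
    ts <- seq(0.25, maxarc, by = 0.25)
    tb <- NA_real_
    for (t in ts) {
      q <- round(p + t * v)
      if (q[1] < 1 || q[2] < 1 || q[1] > nr || q[2] > nc ||
          !mask[q[1], q[2]]) { tb <- t; break }
    }
    if (is.na(tb)) next          # no cap within reach (tip inside a blob)
    target <- tb - rhat + tip_offset
    if (target <= 0) next
    # digital straight extension to the cap-center pixel keeps pixel counts
    # orientation-consistent with the rest of the skeleton
    qc <- round(p + target * v)
    ext <- bresenham(p, qc)
    if (nrow(ext) < 2) next
    for (i in 2:nrow(ext)) {
      q <- ext[i, ]
      if (q[1] < 1 || q[2] < 1 || q[1] > nr || q[2] > nc) break
      if (!mask[q[1], q[2]] || skel[q[1], q[2]]) break
      # do not fuse with unrelated structures
      nbm <- skel[max(1, q[1] - 1):min(nr, q[1] + 1),
                  max(1, q[2] - 1):min(nc, q[2] + 1)]
      if (sum(nbm) > 1) break
      skel[q[1], q[2]] <- TRUE
    }
  }
  skel
}

#' Analysis configuration
#'
#' Bundles the tunable parameters of the measurement pipeline.
#'
#' @param threshold_method mask segmentation rule: `"otsu"` (default; a
#'   control-percentile threshold sits just above background and would
#'   admit the entire PSF skirt of bright structures), `"negative_control"`,
#'   or `NULL` to pick `"negative_control"` whenever the field carries
#'   control images.
#' @param control_quantile negative-control threshold quantile.
#' @param min_object_px components smaller than this are removed before
#'   skeletonization.
#' @param pixel_size micrometres per pixel; `NULL` uses the field's value.
#' @param closing_radius radius (px) of the closing element used to build
#'   the whole-cell mask.
#' @param junction_merge_px junction nodes bridged by internal branches of
#'   at most this many pixels are merged (thinning-artifact scale, about
#'   the junction blob radius); `NULL` derives it from the mask's medial
#'   half-width `r` as `r + 1`.
#' @param cap_correction extend skeleton tips to tube end caps before
#'   measuring (see [extend_skeleton_tips()]).
#' @param alpha significance level for the inference layer.
#' @return list of class `mn_config`.
#' @export
mn_config <- function(threshold_method = "otsu", control_quantile = 0.995,
                      min_object_px = 5, pixel_size = NULL,
                      closing_radius = 7, junction_merge_px = NULL,
                      cap_correction = TRUE, alpha = 0.05) {
  stopifnot(min_object_px >= 1, control_quantile > 0, control_quantile < 1,
            alpha > 0, alpha < 1,
            is.null(junction_merge_px) || junction_merge_px >= 0)
  structure(list(threshold_method = threshold_method,
                 control_quantile = control_quantile,
                 min_object_px = min_object_px,
                 pixel_size = pixel_size,
                 closing_radius = closing_radius,
                 junction_merge_px = junction_merge_px,
                 cap_correction = isTRUE(cap_correction),
                 alpha = alpha),
            class = "mn_config")
}

#' Measure mitochondrial morphology on one field
#'
#' Runs the full single-field morphology pipeline on the mitochondrial
#' marker channel: threshold, small-object removal, skeletonization, graph
#' extraction, metrics. Blank or threshold-failing fields yield a flagged
#' record with `NA` metrics, never an error.
#'
#' @param field a `fluorescence_field` (see [render_field()] or
#'   [read_field()]).
#' @param config an [mn_config()].
#' @return one-row `data.frame`: condition labels, branch/junction/rod
#'   counts, fragmentation, branching, `mean_branch_length_um`, `qc_flag`.
#' @export
measure_field <- function(field, config = mn_config()) {
  stopifnot(inherits(field, "fluorescence_field"))
  ctrl <- field$controls$mito
  method <- config$threshold_method
  if (is.null(method)) method <- if (is.null(ctrl)) "otsu" else "negative_control"
  px <- if (is.null(config$pixel_size)) field$pixel_size else config$pixel_size

  mask <- threshold_mask(field$mito, negative_control = ctrl, method = method,
                         control_quantile = config$control_quantile)
  mask <- clean_mask(mask, config$min_object_px)
  flag <- ""
  if (!any(mask)) {
    flag <- "empty_mask"
    g <- build_graph(matrix(FALSE, nrow(field$mito), ncol(field$mito)))
  } else {
    skel <- skeletonize(mask)
    merge_px <- config$junction_merge_px
    if (is.null(merge_px)) {
      # thinning splits a thick junction blob into clusters roughly one
      # medial radius apart, so that is the bridge scale to absorb; real
      # branches must stay clearly above it
      dm <- EBImage::imageData(EBImage::distmap(EBImage::Image(mask * 1)))
      merge_px <- ceiling(median(dm[skel])) + 1
    }
    if (config$cap_correction) skel <- extend_skeleton_tips(skel, mask)
    g <- build_graph(skel, junction_merge_px = merge_px)
    if (length(g$qc_flags)) flag <- paste(g$qc_flags, collapse = ";")
  }
  frag <- br <- mbl <- NA_real_
  if (g$branch_count > 0) {
    frag <- g$rod_count / g$branch_count
    br <- g$junction_count / g$branch_count
    mbl <- mean(g$branch_lengths_px) * px
  } else if (flag == "") flag <- "no_branches"
  data.frame(field_id = field$field_id %||% NA_character_,
             replicate = field$replicate_id %||% NA_character_,
             katp_level = field$katp_level %||% NA_character_,
             rotenone = field$rotenone %||% NA_character_,
             branch_count = g$branch_count,
             junction_count = g$junction_count,
             rod_count = g$rod_count,
             fragmentation = frag,
             branching = br,
             mean_branch_length_um = mbl,
             qc_flag = flag,
             stringsAsFactors = FALSE)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
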