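# Ground-truth skeleton generation.
#
# Networks are unions of digital straight segments (8-connected Bresenham
# lines). Junction-bearing components are trees: junctions of degree 3 (roots
# may have degree 4), connected by junction-junction edges and finished with
# leaf arms; rods are isolated segments. Local geometry is constrained so the
# drawn pixel set is exactly 1 pixel wide under the 8-neighbour rule: every
# junction's incident arms start in pairwise non-adjacent cells of its
# 3x3 ring, and a minimum spacing is kept between non-incident structures so
# that tube rendering + re-thinning cannot merge them.

ring_offsets <- rbind(c(-1, 0), c(-1, 1), c(0, 1), c(1, 1),
                      c(1, 0), c(1, -1), c(0, -1), c(-1, -1))

# subsets of ring cells, pairwise non-adjacent (chebyshev distance > 1),
# indexed by subset size
ring_sets_of_size <- local({
  adj <- function(i, j) {
    max(abs(ring_offsets[i, ] - ring_offsets[j, ])) <= 1
  }
  out <- list()
  for (d in 1:4) {
    combs <- utils::combn(8, d)
    keep <- apply(combs, 2, function(s) {
      if (length(s) == 1) return(TRUE)
      prs <- utils::combn(s, 2)
      all(!apply(prs, 2, function(p) adj(p[1], p[2])))
    })
    out[[d]] <- combs[, keep, drop = FALSE]
  }
  out
})

ring_index <- function(offset) {
  which(ring_offsets[, 1] == offset[1] & ring_offsets[, 2] == offset[2])
}

# 8-connected digital straight segment between integer points (inclusive)
bresenham <- function(p, q) {
  r0 <- p[1]; c0 <- p[2]; r1 <- q[1]; c1 <- q[2]
  dr <- abs(r1 - r0); dc <- abs(c1 - c0)
  sr <- if (r1 >= r0) 1L else -1L
  sc <- if (c1 >= c0) 1L else -1L
  n <- max(dr, dc) + 1L
  out <- matrix(0L, n, 2)
  err <- dc - dr
  r <- r0; c <- c0
  for (i in seq_len(n)) {
    out[i, ] <- c(r, c)
    if (r == r1 && c == c1) break
    e2 <- 2L * err
    if (e2 > -dr) { err <- err - dr; c <- c + sc }
    if (e2 < dc)  { err <- err + dc; r <- r + sr }
  }
  out
}

new_net_state <- function(image_shape, min_spacing) {
  env <- new.env(parent = emptyenv())
  env$pts <- matrix(integer(0), 0, 2)
  env$comp <- integer(0)
  env$exp_deg <- integer(0)
  # anchor junction per pixel (up to two, for junction-junction edges):
  # pixels may come closer than min_spacing only to pixels sharing an
  # anchor, i.e. sibling structure around one junction
  env$anch <- matrix(NA_integer_, 0, 4)
  env$shape <- image_shape
  env$spacing <- min_spacing
  # exemption radius around the shared junction; beyond it the >= 60 degree
  # angular separation of sibling arms guarantees adequate clearance
  env$clear <- 2 * min_spacing
  env
}

# Try to add a segment. seg excludes already-placed attachment junctions;
# attach: matrix of attachment junction pixels (0-2 rows; for a
# junction-junction edge the new junction at the segment's end is the
# second row).
seg_ok <- function(st, seg, attach, comp_id) {
  sh <- st$shape
  if (any(seg[, 1] < 3 | seg[, 2] < 3 |
          seg[, 1] > sh[1] - 2 | seg[, 2] > sh[2] - 2)) return(FALSE)
  if (nrow(st$pts) == 0) return(TRUE)
  D <- pmax(abs(outer(seg[, 1], st$pts[, 1], "-")),
            abs(outer(seg[, 2], st$pts[, 2], "-")))
  bad <- which(D < st$spacing, arr.ind = TRUE)
  if (nrow(bad) == 0) return(TRUE)
  has_attach <- !is.null(attach) && nrow(attach) > 0
  for (k in seq_len(nrow(bad))) {
    i <- bad[k, 1]; j <- bad[k, 2]
    d <- D[i, j]
    if (d <= 1) {
      # adjacency/overlap: only the first segment pixel may touch the
      # attachment junction, and exactly at distance 1
      if (d == 0) return(FALSE)
      if (!(has_attach && i == 1 &&
            st$pts[j, 1] == attach[1, 1] && st$pts[j, 2] == attach[1, 2]))
        return(FALSE)
    } else {
      # sub-spacing proximity: both pixels must be siblings around the same
      # attachment junction of this segment
      if (st$comp[j] != comp_id || !has_attach) return(FALSE)
      ok <- FALSE
      am <- st$anch[j, ]
      for (a in seq_len(nrow(attach))) {
        A <- attach[a, ]
        if (max(abs(seg[i, ] - A)) > st$clear) next
        if (isTRUE(am[1] == A[1] && am[2] == A[2]) ||
            isTRUE(am[3] == A[1] && am[4] == A[2])) {
          ok <- TRUE; break
        }
      }
      if (!ok) return(FALSE)
    }
  }
  TRUE
}

add_seg <- function(st, seg, comp_id, exp_deg, attach = NULL) {
  n <- nrow(seg)
  anch <- matrix(NA_integer_, n, 4)
  if (!is.null(attach) && nrow(attach) > 0) {
    for (a in seq_len(min(nrow(attach), 2))) {
      A <- attach[a, ]
      near <- pmax(abs(seg[, 1] - A[1]), abs(seg[, 2] - A[2])) <= st$clear
      slot <- if (a == 1) 1:2 else 3:4
      anch[near, slot[1]] <- A[1]
      anch[near, slot[2]] <- A[2]
    }
  }
  st$pts <- rbind(st$pts, seg)
  st$comp <- c(st$comp, rep(comp_id, n))
  st$exp_deg <- c(st$exp_deg, exp_deg)
  st$anch <- rbind(st$anch, anch)
  invisible(st)
}

# draw one outward segment from junction P starting in ring cell `cell`,
# at jittered angle, length ~ U(length_range); returns seg pixels
# (excluding P) or NULL
draw_outward <- function(st, P, cell, length_range, comp_id,
                         tries = 40) {
  base_ang <- atan2(ring_offsets[cell, 1], ring_offsets[cell, 2])
  s1 <- P + ring_offsets[cell, ]
  for (t in seq_len(tries)) {
    ang <- base_ang + runif(1, -15, 15) * pi / 180
    len <- runif(1, length_range[1], length_range[2])
    e <- round(c(P[1] + len * sin(ang), P[2] + len * cos(ang)))
    if (all(e == s1)) next
    seg <- bresenham(s1, e)
    if (nrow(seg) < 3) next
    if (seg_ok(st, seg, matrix(P, 1, 2), comp_id)) return(seg)
  }
  NULL
}

place_tree <- function(st, n_junc, root_d, length_range, comp_id,
                       tries = 60) {
  sh <- st$shape
  sets <- ring_sets_of_size
  root <- NULL
  for (t in seq_len(tries)) {
    cand <- c(sample(3:(sh[1] - 2), 1), sample(3:(sh[2] - 2), 1))
    if (seg_ok(st, matrix(cand, 1, 2), NULL, comp_id)) { root <- cand; break }
  }
  if (is.null(root)) return(NULL)
  add_seg(st, matrix(root, 1, 2), comp_id, root_d,
          attach = matrix(root, 1, 2))

  pick_set <- function(d, must_contain = NULL) {
    s <- sets[[d]]
    if (!is.null(must_contain)) {
      s <- s[, apply(s, 2, function(x) must_contain %in% x), drop = FALSE]
    }
    if (ncol(s) == 0) return(NULL)
    s[, sample.int(ncol(s), 1)]
  }

  junctions <- list(list(pos = root, d = root_d))
  root_cells <- pick_set(root_d)
  slots <- lapply(root_cells, function(cl) list(j = 1L, cell = cl))
  edges <- list()   # branch bookkeeping: list(kind, npix)

  # attach remaining junctions to random open slots
  n_left <- n_junc - 1L
  while (n_left > 0) {
    if (length(slots) == 0) return(NULL)
    placed <- FALSE
    for (t in seq_len(tries)) {
      si <- sample.int(length(slots), 1)
      sl <- slots[[si]]
      P <- junctions[[sl$j]]$pos
      seg <- draw_outward(st, P, sl$cell, length_range, comp_id)
      if (is.null(seg)) next
      q <- seg[nrow(seg), ]
      inc <- ring_index(seg[nrow(seg) - 1, ] - q)
      qset <- pick_set(3L, must_contain = inc)
      if (is.null(qset)) next
      exp <- c(rep(2L, nrow(seg) - 1), 3L)
      add_seg(st, seg, comp_id, exp, attach = rbind(P, q))
      junctions[[length(junctions) + 1L]] <- list(pos = q, d = 3L)
      slots <- slots[-si]
      free <- setdiff(qset, inc)
      for (cl in free) {
        slots[[length(slots) + 1L]] <- list(j = length(junctions), cell = cl)
      }
      edges[[length(edges) + 1L]] <- list(kind = "edge", npix = nrow(seg) + 1L)
      placed <- TRUE
      break
    }
    if (!placed) return(NULL)
    n_left <- n_left - 1L
  }

  # leaf arms on all remaining slots
  for (sl in slots) {
    P <- junctions[[sl$j]]$pos
    seg <- draw_outward(st, P, sl$cell, length_range, comp_id)
    if (is.null(seg)) return(NULL)
    exp <- c(rep(2L, nrow(seg) - 1), 1L)
    if (nrow(seg) == 1) exp <- 1L
    add_seg(st, seg, comp_id, exp, attach = matrix(P, 1, 2))
    edges[[length(edges) + 1L]] <- list(kind = "arm", npix = nrow(seg) + 1L)
  }
  list(junctions = junctions, edges = edges)
}

place_rod <- function(st, length_range, comp_id, tries = 80) {
  sh <- st$shape
  for (t in seq_len(tries)) {
    p <- c(sample(3:(sh[1] - 2), 1), sample(3:(sh[2] - 2), 1))
    ang <- runif(1, 0, 2 * pi)
    len <- runif(1, length_range[1], length_range[2])
    e <- round(c(p[1] + len * sin(ang), p[2] + len * cos(ang)))
    seg <- bresenham(p, e)
    if (nrow(seg) < 2) next
    if (!seg_ok(st, seg, NULL, comp_id)) next
    exp <- c(1L, rep(2L, nrow(seg) - 2), 1L)
    add_seg(st, seg, comp_id, exp)
    return(nrow(seg))
  }
  NULL
}

#' Generate a ground-truth mitochondrial skeleton network
#'
#' Draws a random 1-pixel-wide skeleton with exactly the requested topology:
#' `n_rods` solitary rod components, and junction-bearing tree components
#' holding the remaining `n_branches - n_rods` branches meeting at
#' `n_junctions` junction points. The construction is self-validating: the
#' returned skeleton's 8-neighbour degree map is checked against the
#' intended one, so graph extraction recovers the counts exactly and
#' re-skeletonizing the skeleton is a no-op.
#'
#' Feasibility: with `m = n_branches - n_rods`, either `n_junctions = 0` and
#' `m = 0`, or `2*n_junctions + 1 <= m <= 4*n_junctions` (junctions have
#' degree 3, with degree-4 tree roots used to absorb surplus branches).
#'
#' @param n_branches total branch count (rods included; each rod is one
#'   branch).
#' @param n_junctions junction count.
#' @param n_rods solitary rod count (`<= n_branches`).
#' @param length_range branch length range in pixels.
#' @param image_shape `c(rows, cols)` of the target field.
#' @param seed integer seed (`NULL`: current RNG stream).
#' @param min_spacing minimum chebyshev distance between non-incident
#'   structures; keep at `>= 2*tube_radius + 3*psf_sigma + 2` of the
#'   intended rendering (the extra margin covers threshold-induced mask
#'   dilation) so distinct components never merge after blurring and
#'   re-thresholding.
#' @param max_tries full restarts before giving up with a packing error.
#' @return `ground_truth_network`: list with `skeleton` (logical matrix),
#'   `true_branch_count`, `true_junction_count`, `true_rod_count`,
#'   `true_branch_lengths` (pixel counts, same terminal-pixel convention as
#'   [mean_branch_length()]), `junction_pixels`, `image_shape`.
#' @export
generate_network <- function(n_branches, n_junctions, n_rods,
                             length_range = c(15, 50),
                             image_shape = c(512, 512),
                             seed = NULL, min_spacing = 9,
                             max_tries = 50) {
  stopifnot(n_branches >= 0, n_junctions >= 0, n_rods >= 0,
            n_rods <= n_branches, length(image_shape) == 2,
            length_range[1] >= 5, length_range[2] >= length_range[1],
            min_spacing >= 2)
  m <- n_branches - n_rods
  if (n_junctions == 0 && m != 0) {
    stop("infeasible topology: branches beyond rods require junctions")
  }
  if (n_junctions > 0 && (m < 2 * n_junctions + 1 || m > 4 * n_junctions)) {
    stop("infeasible topology: need 2*J+1 <= branches-rods <= 4*J")
  }

  with_seed(seed, {
    for (attempt in seq_len(max_tries)) {
      st <- new_net_state(image_shape, min_spacing)
      ok <- TRUE
      lengths <- numeric(0)
      jpix <- matrix(integer(0), 0, 2)
      comp_id <- 0L

      if (n_junctions > 0) {
        # a tree with j degree-3 junctions holds 2j+1 branches; upgrading its
        # root to degree 4 absorbs one more, so c trees cover
        # m in [2J + c, 2J + 2c]; pick the smallest feasible c
        c_trees <- max(1L, as.integer(ceiling((m - 2 * n_junctions) / 2)))
        n_d4 <- m - 2L * n_junctions - c_trees   # roots upgraded to degree 4
        j_per <- rep(n_junctions %/% c_trees, c_trees)
        if (n_junctions %% c_trees > 0) {
          j_per[seq_len(n_junctions %% c_trees)] <-
            j_per[seq_len(n_junctions %% c_trees)] + 1L
        }
        root_d <- c(rep(4L, n_d4), rep(3L, c_trees - n_d4))
        for (tct in seq_len(c_trees)) {
          comp_id <- comp_id + 1L
          res <- place_tree(st, j_per[tct], root_d[tct], length_range, comp_id)
          if (is.null(res)) { ok <- FALSE; break }
          lengths <- c(lengths, vapply(res$edges, `[[`, 0, "npix"))
          jpix <- rbind(jpix, do.call(rbind,
                        lapply(res$junctions, function(j) j$pos)))
        }
      }
      if (ok && n_rods > 0) {
        for (rr in seq_len(n_rods)) {
          comp_id <- comp_id + 1L
          npix <- place_rod(st, length_range, comp_id)
          if (is.null(npix)) { ok <- FALSE; break }
          lengths <- c(lengths, npix)
        }
      }
      if (!ok) next

      skel <- matrix(FALSE, image_shape[1], image_shape[2])
      skel[st$pts] <- TRUE
      deg <- nbr_count8(as_binary_int(skel))
      if (!all(deg[st$pts] == st$exp_deg)) next
      if (sum(skel) != nrow(st$pts)) next

      net <- list(skeleton = skel,
                  true_branch_count = as.integer(n_branches),
                  true_junction_count = as.integer(n_junctions),
                  true_rod_count = as.integer(n_rods),
                  true_branch_lengths = as.numeric(lengths),
                  junction_pixels = jpix,
                  image_shape = as.integer(image_shape),
                  min_spacing = min_spacing)
      class(net) <- "ground_truth_network"
      return(net)
    }
    stop("could not place requested topology in image_shape (", max_tries,
         " attempts); image too small for requested topology")
  })
}

#' @export
print.ground_truth_network <- function(x, ...) {
  cat("ground-truth network:", x$true_branch_count, "branches,",
      x$true_junction_count, "junctions,", x$true_rod_count, "rods on",
      paste(x$image_shape, collapse = "x"), "grid\n")
  invisible(x)
}
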