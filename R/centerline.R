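#' Centerline tree of a segmented vessel
#'
#' Nodes are world-mm positions with arc-length from the root (the aorta
#' attachment), a local radius estimate from the distance transform, a unit
#' tangent, and parent links forming a tree (no cycles, `n - 1` edges).
#'
#' @param nodes tibble with columns `node`, `parent` (`NA` for the root),
#'   `x`, `y`, `z` (mm), `arc_mm`, `radius_mm`, `tx`, `ty`, `tz`,
#'   `n_children`, `is_bifurcation`.
#' @return object of class `centerline_tree`.
#' @keywords internal
centerline_tree <- function(nodes) {
  stopifnot(sum(is.na(nodes$parent)) == 1L)
  structure(list(nodes = nodes, root = nodes$node[is.na(nodes$parent)]),
            class = "centerline_tree")
}

#' @export
print.centerline_tree <- function(x, ...) {
  n <- nrow(x$nodes)
  cat(sprintf("<centerline_tree> %d nodes, %d bifurcation(s), length %.1f mm\n",
              n, sum(x$nodes$is_bifurcation), max(x$nodes$arc_mm)))
  invisible(x)
}

# assemble the node table from traced voxel paths:
# paths: list of list(voxels = linear idx (attachment first), attach_node = id
# or NA for the first path). Positions smoothed per path (ends fixed), then
# arc-lengths, tangents and child counts computed.
build_tree_nodes <- function(paths, dims, spacing, origin, dt, smooth_window = 5L) {
  idx_to_mm <- function(idx0) {
    x <- idx0 %% dims[1]
    y <- (idx0 %/% dims[1]) %% dims[2]
    z <- idx0 %/% (dims[1] * dims[2])
    cbind(origin[1] + x * spacing[1], origin[2] + y * spacing[2],
          origin[3] + z * spacing[3])
  }
  smooth_chain <- function(P) {
    n <- nrow(P)
    if (n < 4 || smooth_window < 3) return(P)
    w <- min(smooth_window, if (n %% 2) n else n - 1L)
    half <- (w - 1L) %/% 2L
    Q <- P
    for (j in 1:3) {
      sm <- stats::filter(P[, j], rep(1 / w, w), sides = 2)
      keep <- !is.na(sm)
      Q[keep, j] <- sm[keep]
    }
    Q[1, ] <- P[1, ]; Q[n, ] <- P[n, ]
    # blend the near-end rows back towards the raw positions
    for (m in seq_len(min(half, n - 2))) {
      a <- m / (half + 1)
      Q[1 + m, ] <- a * Q[1 + m, ] + (1 - a) * P[1 + m, ]
      Q[n - m, ] <- a * Q[n - m, ] + (1 - a) * P[n - m, ]
    }
    Q
  }

  node_id <- integer(0); parent <- integer(0)
  pos <- matrix(numeric(0), ncol = 3); radius <- numeric(0)
  voxel_of <- integer(0)
  next_id <- 1L
  voxel_node <- new.env(parent = emptyenv())  # voxel idx -> node id

  for (p in paths) {
    vox <- p$voxels
    P <- smooth_chain(idx_to_mm(vox))
    start <- 1L
    prev <- p$attach_node
    if (!is.na(prev)) start <- 2L  # attachment voxel already exists as a node
    for (i in start:length(vox)) {
      id <- next_id; next_id <- next_id + 1L
      node_id <- c(node_id, id)
      parent <- c(parent, if (i == 1L) NA_integer_ else prev)
      pos <- rbind(pos, P[i, ])
      radius <- c(radius, dt[vox[i] + 1L])
      voxel_of <- c(voxel_of, vox[i])
      assign(as.character(vox[i]), id, envir = voxel_node)
      prev <- id
    }
  }

  nodes <- tibble::tibble(
    node = node_id, parent = parent,
    x = pos[, 1], y = pos[, 2], z = pos[, 3],
    radius_mm = radius, voxel = voxel_of
  )
  n <- nrow(nodes)
  # arc length from root via parent chain (parents always precede children)
  arc <- numeric(n)
  for (i in seq_len(n)) {
    p <- nodes$parent[i]
    arc[i] <- if (is.na(p)) 0 else {
      arc[p] + sqrt(sum((pos[i, ] - pos[p, ])^2))
    }
  }
  nodes$arc_mm <- arc
  nchild <- tabulate(nodes$parent[!is.na(nodes$parent)], nbins = n)
  nodes$n_children <- nchild
  nodes$is_bifurcation <- nchild >= 2L
  # tangents: central difference parent -> first child, one-sided at ends
  first_child <- rep(NA_integer_, n)
  for (i in seq_len(n)) {
    p <- nodes$parent[i]
    if (!is.na(p) && is.na(first_child[p])) first_child[p] <- i
  }
  tg <- matrix(0, n, 3)
  for (i in seq_len(n)) {
    a <- nodes$parent[i]; b <- first_child[i]
    if (is.na(a)) a <- i
    if (is.na(b)) b <- i
    v <- pos[b, ] - pos[a, ]
    nv <- sqrt(sum(v^2))
    tg[i, ] <- if (nv > 0) v / nv else c(1, 0, 0)
  }
  nodes$tx <- tg[, 1]; nodes$ty <- tg[, 2]; nodes$tz <- tg[, 3]
  nodes
}

#' Extract the centerline tree of a labelled vessel
#'
#' Medial-path centerline: the exact anisotropic Euclidean distance transform
#' of the label provides a medialness weight; branches are traced iteratively
#' as minimum-cost paths (cost = mm step scaled by inverse squared medialness)
#' from the geodesically farthest unexplained voxel back to the growing tree,
#' until every remaining voxel lies within the local vessel radius plus the
#' spur-pruning length of the tree. This favours paths that hug the medial
#' axis while guaranteeing a single-voxel-wide tree (`n - 1` edges) whose
#' nodes all lie inside the label.
#'
#' @param labels a `label_volume` from [fuzzy_connectedness_segment()].
#' @param root_hint world mm position near the aorta attachment; the root is
#'   the labelled voxel nearest to it.
#' @param label which label to trace (default: any non-zero).
#' @param prune_mm spurs shorter than this beyond the local radius are not
#'   traced (default 2 mm).
#' @param smooth_window moving-average window (nodes) for de-jittering voxel
#'   chains; ends pinned.
#' @param max_branches safety cap on traced branches.
#' @return a `centerline_tree`.
#' @export
extract_centerline <- function(labels, root_hint, label = NULL, prune_mm = 2,
                               smooth_window = 7L, max_branches = 12L) {
  stopifnot(inherits(labels, "label_volume"))
  mask <- label_mask(labels, label)
  if (!any(mask)) stop("the requested label is empty")
  dims <- dim(labels$labels)
  sp <- labels$spacing
  org <- labels$origin

  dt <- edt_cpp(mask, dims, sp)
  w <- 1 / (dt + 0.5)^2

  idx1 <- which(mask)                       # 1-based linear indices
  coords <- arrayInd(idx1, dims)
  mm <- sweep(sweep(coords - 1, 2, sp, "*"), 2, org, "+")
  root1 <- idx1[which.min(colSums((t(mm) - root_hint)^2))]

  tree_vox0 <- as.integer(root1 - 1L)       # 0-based for C++
  paths <- list()
  vox_node_count <- 0L

  repeat {
    g <- geodesic_cpp(mask, dims, sp, tree_vox0, numeric(0))
    gc_ <- g$cost
    gc_[!mask | !is.finite(gc_)] <- -Inf  # other components are not traced
    # anchor tips medially: maximize geodesic distance plus local radius, so a
    # branch ends on the axis of its end face rather than on the rim
    far1 <- which.max(gc_ + ifelse(is.finite(gc_), dt, 0))
    far_dist <- gc_[far1]
    if (!is.finite(far_dist)) break
    cw <- geodesic_cpp(mask, dims, sp, tree_vox0, w)
    # walk predecessors from the far voxel back to the tree
    chain <- integer(0)
    cur <- as.integer(far1 - 1L)
    while (cur >= 0L && !(cur %in% tree_vox0)) {
      chain <- c(cur, chain)
      cur <- cw$pred[cur + 1L]
    }
    attach0 <- if (cur >= 0L) cur else chain[1]
    if (far_dist <= prune_mm + dt[attach0 + 1L]) break
    paths[[length(paths) + 1L]] <- list(voxels = c(attach0, chain),
                                        attach0 = attach0)
    tree_vox0 <- c(tree_vox0, chain)
    if (length(paths) >= max_branches) break
  }

  if (length(paths) == 0) {
    # degenerate label (single blob): a one-node tree at the root
    paths <- list(list(voxels = as.integer(root1 - 1L), attach0 = NA_integer_))
  }

  # resolve attachments to node ids: first path roots the tree
  vox_seen <- integer(0)
  tree_paths <- list()
  for (i in seq_along(paths)) {
    p <- paths[[i]]
    if (i == 1L) {
      tree_paths[[i]] <- list(voxels = p$voxels, attach_node = NA_integer_)
    } else {
      tree_paths[[i]] <- list(voxels = p$voxels,
                              attach_node = match(p$voxels[1], vox_seen))
    }
    new_vox <- if (i == 1L) p$voxels else p$voxels[-1]
    vox_seen <- c(vox_seen, new_vox)
  }

  nodes <- build_tree_nodes(tree_paths, dims, sp, org, dt, smooth_window)
  centerline_tree(nodes)
}

# follow the chain from `from` (inclusive) until an effective bifurcation or a
# tip; the first step can be constrained to `via`. `eff_children` filters out
# sub-threshold spur branches so they neither end the walk nor divert it.
walk_chain <- function(nodes, from, via = NA_integer_,
                       eff_children = NULL) {
  if (is.null(eff_children))
    eff_children <- function(id)
      nodes$node[!is.na(nodes$parent) & nodes$parent == id]
  out <- from
  cur <- from
  step <- via
  repeat {
    ch <- eff_children(cur)
    nxt <- if (!is.na(step)) step else if (length(ch) == 1L) ch else break
    step <- NA_integer_
    out <- c(out, nxt)
    cur <- nxt
    if (length(eff_children(cur)) != 1L) break
  }
  out
}

subtree_length <- function(nodes, id) {
  children <- nodes$node[!is.na(nodes$parent) & nodes$parent == id]
  edge <- function(a, b) {
    ia <- match(a, nodes$node); ib <- match(b, nodes$node)
    sqrt((nodes$x[ia] - nodes$x[ib])^2 + (nodes$y[ia] - nodes$y[ib])^2 +
           (nodes$z[ia] - nodes$z[ib])^2)
  }
  if (!length(children)) return(0)
  sum(vapply(children, function(c2) edge(id, c2) + subtree_length(nodes, c2),
             numeric(1)))
}

#' Define the measurable segments of an artery centerline
#'
#' Segment 1 runs from the aorta attachment (the root) to the most proximal
#' bifurcation, or to the vessel end if the artery never branches. Segment 2
#' follows the largest branch (largest mean radius estimate over its first
#' 5 mm) from the first bifurcation to the second bifurcation or branch tip.
#' Each node carries its distance to the aorta (arc-length from the root) and
#' the segments record their bounding bifurcation arc-lengths, which the
#' profiling stage uses for the maximum-eligibility rules.
#'
#' @param tree a `centerline_tree` rooted at the aorta attachment.
#' @param artery_id identifier stored on the segments.
#' @param min_branch_mm a side branch whose whole subtree is shorter than this
#'   is treated as a centerline spur (residual segmentation bleed at the
#'   aorta wall or surface noise), not an anatomical bifurcation; a renal
#'   artery branch is always longer. Default 3 mm.
#' @return list of `vessel_segment` objects (1 or 2 elements).
#' @export
define_segments <- function(tree, artery_id = 1L, min_branch_mm = 3) {
  nodes <- tree$nodes
  children_raw <- function(id)
    nodes$node[!is.na(nodes$parent) & nodes$parent == id]
  children <- function(id) {
    ch <- children_raw(id)
    if (length(ch) < 2L) return(ch)
    keep <- vapply(ch, function(k) {
      r <- match(k, nodes$node)
      edge <- sqrt((nodes$x[r] - nodes$x[match(id, nodes$node)])^2 +
                     (nodes$y[r] - nodes$y[match(id, nodes$node)])^2 +
                     (nodes$z[r] - nodes$z[match(id, nodes$node)])^2)
      edge + subtree_length(nodes, k) >= min_branch_mm
    }, logical(1))
    if (!any(keep)) ch else ch[keep]
  }

  root <- tree$root
  root_kids <- children(root)
  first_step <- if (length(root_kids) > 1L) {
    # branches at the root itself are segmentation bleed into the aorta:
    # follow the dominant (longest) subtree
    root_kids[which.max(vapply(root_kids, function(k)
      subtree_length(nodes, k), numeric(1)))]
  } else if (length(root_kids) == 1L) root_kids else NA_integer_

  seg1_ids <- if (is.na(first_step)) root
    else walk_chain(nodes, root, first_step, eff_children = children)
  end1 <- seg1_ids[length(seg1_ids)]
  end1_row <- match(end1, nodes$node)
  has_bif <- length(children(end1)) >= 2L

  make_segment <- function(ids, seg_idx, start_bif, end_bif) {
    df <- nodes[match(ids, nodes$node), ]
    df$dist_aorta_mm <- df$arc_mm
    structure(df, segment = seg_idx, artery = artery_id,
              start_bif_mm = start_bif, end_bif_mm = end_bif,
              class = c("vessel_segment", class(df)))
  }

  seg1 <- make_segment(seg1_ids, 1L, NA_real_,
                       if (has_bif) nodes$arc_mm[end1_row] else NA_real_)
  if (!has_bif) return(list(seg1))

  # largest branch from the first bifurcation: mean radius over first 5 mm
  kids <- children(end1)
  branch_score <- vapply(kids, function(k) {
    ids <- walk_chain(nodes, end1, via = k, eff_children = children)
    rows <- match(ids, nodes$node)
    within5 <- nodes$arc_mm[rows] - nodes$arc_mm[end1_row] <= 5
    r <- nodes$radius_mm[rows][within5]
    if (all(is.na(r))) subtree_length(nodes, k) else mean(r, na.rm = TRUE)
  }, numeric(1))
  pick <- kids[which.max(branch_score)]
  seg2_ids <- walk_chain(nodes, end1, via = pick, eff_children = children)
  end2 <- seg2_ids[length(seg2_ids)]
  end2_bif <- length(children(end2)) >= 2L
  seg2 <- make_segment(seg2_ids, 2L, nodes$arc_mm[end1_row],
                       if (end2_bif) nodes$arc_mm[match(end2, nodes$node)]
                       else NA_real_)
  list(seg1, seg2)
}

# --- manual centerline I/O ---------------------------------------------------

#' Import a manually drawn centerline
#'
#' Reads a JSON description of branch polylines (the fallback used when the
#' automatic centerline is obviously wrong and the curve has to be drawn by
#' hand) and returns the same `centerline_tree` contract as
#' [extract_centerline()], with tangents recomputed by central differences.
#' Schema: `{"branches": [{"id": 1, "parent": null, "points": [[x,y,z], ...]},
#' {"id": 2, "parent": 1, "points": ...}, ...]}` with positions in world mm; a
#' child branch's first point must coincide with a point of its parent branch
#' (nearest node is used as the attachment).
#'
#' @param path JSON file path.
#' @return a `centerline_tree` (radius estimates are `NA`).
#' @export
import_manual_centerline <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  brs <- obj$branches
  if (is.data.frame(brs)) brs <- split(brs, seq_len(nrow(brs)))
  get_points <- function(b) {
    p <- if (is.data.frame(b)) b$points[[1]] else b$points
    m <- if (is.list(p)) do.call(rbind, lapply(p, unlist)) else as.matrix(p)
    storage.mode(m) <- "double"
    m
  }
  nodes <- NULL
  next_id <- 1L
  branch_first <- list()
  for (b in brs) {
    P <- get_points(b)
    if (nrow(P) < 2L) stop("a manual centerline branch needs at least 2 points")
    bid <- b$id
    par_branch <- b$parent
    if (is.list(par_branch)) par_branch <- unlist(par_branch)
    if (is.null(par_branch) || length(par_branch) == 0 ||
        all(is.na(par_branch))) {
      attach <- NA_integer_
      start <- 1L
    } else {
      cand <- nodes
      d2 <- (cand$x - P[1, 1])^2 + (cand$y - P[1, 2])^2 + (cand$z - P[1, 3])^2
      attach <- cand$node[which.min(d2)]
      start <- 2L
    }
    prev <- attach
    for (i in start:nrow(P)) {
      nodes <- dplyr::bind_rows(nodes, tibble::tibble(
        node = next_id, parent = prev,
        x = P[i, 1], y = P[i, 2], z = P[i, 3], radius_mm = NA_real_
      ))
      prev <- next_id
      next_id <- next_id + 1L
    }
    branch_first[[as.character(bid)]] <- prev
  }
  n <- nrow(nodes)
  arc <- numeric(n)
  pos <- as.matrix(nodes[, c("x", "y", "z")])
  for (i in seq_len(n)) {
    p <- nodes$parent[i]
    arc[i] <- if (is.na(p)) 0 else arc[p] + sqrt(sum((pos[i, ] - pos[p, ])^2))
  }
  nodes$arc_mm <- arc
  nchild <- tabulate(nodes$parent[!is.na(nodes$parent)], nbins = n)
  nodes$n_children <- nchild
  nodes$is_bifurcation <- nchild >= 2L
  nodes$voxel <- NA_integer_
  first_child <- rep(NA_integer_, n)
  for (i in seq_len(n)) {
    p <- nodes$parent[i]
    if (!is.na(p) && is.na(first_child[p])) first_child[p] <- i
  }
  tg <- matrix(0, n, 3)
  for (i in seq_len(n)) {
    a <- if (is.na(nodes$parent[i])) i else nodes$parent[i]
    b <- if (is.na(first_child[i])) i else first_child[i]
    v <- pos[b, ] - pos[a, ]
    nv <- sqrt(sum(v^2))
    tg[i, ] <- if (nv > 0) v / nv else c(1, 0, 0)
  }
  nodes$tx <- tg[, 1]; nodes$ty <- tg[, 2]; nodes$tz <- tg[, 3]
  centerline_tree(nodes)
}

#' Export a centerline tree to the manual-centerline JSON schema
#'
#' @param tree a `centerline_tree`.
#' @param path output JSON path.
#' @return `path`, invisibly. Re-importing reproduces the node positions.
#' @export
write_centerline <- function(tree, path) {
  nodes <- tree$nodes
  children <- function(id) nodes$node[!is.na(nodes$parent) & nodes$parent == id]
  branches <- list()
  next_branch <- 1L
  # queue of (start node, via child, parent branch id)
  queue <- list(list(start = tree$root, via = NA_integer_, parent = NULL))
  while (length(queue)) {
    item <- queue[[1]]; queue <- queue[-1]
    ids <- walk_chain(nodes, item$start, item$via)
    rows <- match(ids, nodes$node)
    pts <- unname(as.matrix(nodes[rows, c("x", "y", "z")]))
    branches[[next_branch]] <- list(id = next_branch, parent = item$parent,
                                    points = pts)
    endr <- rows[length(rows)]
    for (k in children(nodes$node[endr]))
      queue <- c(queue, list(list(start = nodes$node[endr], via = k,
                                  parent = next_branch)))
    next_branch <- next_branch + 1L
  }
  jsonlite::write_json(list(branches = branches), path, auto_unbox = TRUE,
                       digits = NA, na = "null")
  invisible(path)
}
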