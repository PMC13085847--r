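# 8-connected neighbor offsets, row/col
.n8 <- cbind(dr = c(-1, -1, -1, 0, 0, 1, 1, 1),
             dc = c(-1, 0, 1, -1, 1, -1, 0, 1))

#' Build a diameter-annotated skeleton graph from a vessel mask
#'
#' Skeletonizes the mask (Zhang-Suen thinning), annotates every skeleton
#' pixel with the local diameter `(2 * EDT - 1) * pixel_size` from the
#' Euclidean distance transform, classifies skeleton pixels into endpoints
#' (1 neighbor), path pixels (2 neighbors) and junctions (>= 3 neighbors,
#' adjacent junction pixels merged into one node), and traces the edges
#' (ordered centerline point sequences) between nodes.
#'
#' @param mask A `vessel_mask` from [segment_vessels()], or a logical
#'   matrix plus `pixel_size`.
#' @param pixel_size um/pixel (taken from the `vessel_mask` if given).
#' @return A `vessel_graph`: list with `nodes` (data.frame: `id`, `x_um`,
#'   `y_um`, `type`, `degree`), `edges` (list of lists with `points`
#'   [n x 2 matrix, um], `diameter_um`, `length_um`, `from`, `to`),
#'   `skeleton` (logical matrix), `pixel_size`, `diameter_map`.
#' @export
build_vessel_graph <- function(mask, pixel_size = NULL) {
  if (inherits(mask, "vessel_mask")) {
    pixel_size <- mask$pixel_size
    mask <- mask$mask
  }
  if (is.null(pixel_size) || pixel_size <= 0) stopf("`pixel_size` required")
  if (!any(mask)) stopf("empty mask")
  skel <- skeletonize(mask)
  empty_graph <- function() {
    warning("mask has no extended structure; empty graph", call. = FALSE)
    structure(list(nodes = data.frame(id = integer(0), x_um = numeric(0),
                                      y_um = numeric(0), type = character(0),
                                      degree = integer(0)),
                   edges = list(), skeleton = skel, pixel_size = pixel_size,
                   diameter_map = local_diameter_map(mask, pixel_size)),
              class = "vessel_graph")
  }
  if (sum(skel) < 2) return(empty_graph())
  dmap <- local_diameter_map(mask, pixel_size)
  nr <- nrow(skel); nc <- ncol(skel)
  px <- which(skel, arr.ind = TRUE)
  key <- function(r, c) (c - 1L) * nr + r
  on <- rep(FALSE, nr * nc); on[key(px[, 1], px[, 2])] <- TRUE
  nbrs <- function(r, c) {
    rr <- r + .n8[, 1]; cc <- c + .n8[, 2]
    ok <- rr >= 1 & rr <= nr & cc >= 1 & cc <= nc
    rr <- rr[ok]; cc <- cc[ok]
    sel <- on[key(rr, cc)]
    cbind(rr[sel], cc[sel])
  }
  deg <- integer(nrow(px))
  for (i in seq_len(nrow(px))) deg[i] <- nrow(nbrs(px[i, 1], px[i, 2]))
  idx_of <- rep(NA_integer_, nr * nc)
  idx_of[key(px[, 1], px[, 2])] <- seq_len(nrow(px))
  is_node_px <- deg != 2
  # merge adjacent junction pixels into single nodes
  node_id_of_px <- rep(NA_integer_, nrow(px))
  nodes <- list(); nid <- 0L
  for (i in seq_len(nrow(px))) {
    if (!is_node_px[i] || !is.na(node_id_of_px[i])) next
    nid <- nid + 1L
    stack <- i; members <- integer(0)
    while (length(stack)) {
      j <- stack[length(stack)]; stack <- stack[-length(stack)]
      if (!is.na(node_id_of_px[j])) next
      node_id_of_px[j] <- nid
      members <- c(members, j)
      if (deg[j] >= 3) {
        # branch pixels within one local vessel radius belong to the same
        # anatomical branch point (thinning can split one junction into
        # several nearby branch pixels inside a wide lumen)
        rad <- max(2, ceiling(dmap[px[j, 1], px[j, 2]] / pixel_size / 2))
        near <- which(is_node_px & deg >= 3 & is.na(node_id_of_px) &
                        abs(px[, 1] - px[j, 1]) <= rad &
                        abs(px[, 2] - px[j, 2]) <= rad)
        stack <- c(stack, near)
      }
    }
    type <- if (any(deg[members] >= 3)) "junction" else "endpoint"
    nodes[[nid]] <- data.frame(
      id = nid,
      x_um = mean((px[members, 2] - 0.5) * pixel_size),
      y_um = mean((px[members, 1] - 0.5) * pixel_size),
      type = type,
      degree = max(deg[members]))
  }
  nodes <- if (length(nodes)) do.call(rbind, nodes) else
    data.frame(id = integer(0), x_um = numeric(0), y_um = numeric(0),
               type = character(0), degree = integer(0))
  # trace edges between node pixels through path pixels
  used <- rep(FALSE, nrow(px)) # path pixels consumed
  edges <- list()
  add_edge <- function(chain_idx, from, to) {
    pts <- cbind(x_um = (px[chain_idx, 2] - 0.5) * pixel_size,
                 y_um = (px[chain_idx, 1] - 0.5) * pixel_size)
    dia <- dmap[cbind(px[chain_idx, 1], px[chain_idx, 2])]
    len <- if (nrow(pts) > 1) {
      sum(sqrt(rowSums((pts[-1, , drop = FALSE] -
                        pts[-nrow(pts), , drop = FALSE])^2)))
    } else 0
    edges[[length(edges) + 1L]] <<- list(points = pts, diameter_um = dia,
                                         length_um = len, from = from, to = to)
  }
  node_px_idx <- which(is_node_px)
  for (i in node_px_idx) {
    nb <- nbrs(px[i, 1], px[i, 2])
    for (q in seq_len(nrow(nb))) {
      j <- idx_of[key(nb[q, 1], nb[q, 2])]
      if (is_node_px[j]) {
        # direct node-node contact: register once (i < j) if different nodes
        if (i < j && node_id_of_px[i] != node_id_of_px[j]) {
          add_edge(c(i, j), node_id_of_px[i], node_id_of_px[j])
        }
        next
      }
      if (used[j]) next
      chain <- c(i, j); used[j] <- TRUE
      prev <- i; cur <- j
      repeat {
        nb2 <- nbrs(px[cur, 1], px[cur, 2])
        nxt <- NA_integer_
        for (t in seq_len(nrow(nb2))) {
          cand <- idx_of[key(nb2[t, 1], nb2[t, 2])]
          if (cand != prev) { nxt <- cand; break }
        }
        if (is.na(nxt)) break # dead end (shouldn't happen on clean skeletons)
        chain <- c(chain, nxt)
        if (is_node_px[nxt]) break
        used[nxt] <- TRUE
        prev <- cur; cur <- nxt
      }
      tail_idx <- chain[length(chain)]
      to <- if (is_node_px[tail_idx]) node_id_of_px[tail_idx] else NA_integer_
      # short connectors inside one merged junction are not edges
      if (!(identical(to, node_id_of_px[i]) && length(chain) <= 12)) {
        add_edge(chain, node_id_of_px[i], to)
      }
    }
  }
  # isolated cycles (no node pixels on them): trace from any unused pixel
  for (i in seq_len(nrow(px))) {
    if (is_node_px[i] || used[i]) next
    chain <- i; used[i] <- TRUE
    prev <- i; cur <- i
    repeat {
      nb2 <- nbrs(px[cur, 1], px[cur, 2])
      nxt <- NA_integer_
      for (t in seq_len(nrow(nb2))) {
        cand <- idx_of[key(nb2[t, 1], nb2[t, 2])]
        if (cand != prev && !used[cand]) { nxt <- cand; break }
      }
      if (is.na(nxt)) break
      chain <- c(chain, nxt); used[nxt] <- TRUE
      prev <- cur; cur <- nxt
    }
    if (length(chain) > 2) add_edge(chain, NA_integer_, NA_integer_)
  }
  structure(list(nodes = nodes, edges = edges, skeleton = skel,
                 pixel_size = pixel_size, diameter_map = dmap),
            class = "vessel_graph")
}

#' @export
print.vessel_graph <- function(x, ...) {
  cat(sprintf("vessel_graph: %d node(s) (%d junction), %d edge(s), %.1f um total length\n",
              nrow(x$nodes), sum(x$nodes$type == "junction"),
              length(x$edges),
              sum(vapply(x$edges, function(e) e$length_um, 0))))
  invisible(x)
}

#' @export
summary.vessel_graph <- function(object, ...) {
  d <- unlist(lapply(object$edges, function(e) e$diameter_um))
  cat(sprintf("vessel_graph: %d edges; diameter median %.2f um (range %.2f-%.2f)\n",
              length(object$edges), stats::median(d), min(d), max(d)))
  invisible(object)
}

# number of connected components of the skeleton graph
graph_components <- function(graph) {
  skel <- graph$skeleton
  lab <- EBImage::bwlabel(EBImage::Image(skel * 1))
  max(as.matrix(EBImage::imageData(lab)))
}
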