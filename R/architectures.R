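#' Candidate coupling architectures
#'
#' The model spaces enumerate directed coupling structures between the left
#' and right CPGs of two or three thoracic segments. Edges fall into three
#' classes: `intra` (contralateral, within one segment), `inter` (ipsilateral,
#' between adjacent segments) and `diag` (diagonal cross connections between
#' segments).
#'
#' Two-segment space (4 nodes, ids 1-7): 1 fully connected; 2 intrasegmental +
#' ipsilateral intersegmental (the "eight-shaped" circular structure);
#' 3 intrasegmental + diagonal cross; 4 ipsilateral intersegmental only;
#' 5 diagonal cross only; 6 intrasegmental only; 7 fully unconnected.
#'
#' Three-segment space (6 nodes, ids 1-4): 1 union of the winning two-segment
#' subnetworks (intrasegmental everywhere + ipsilateral pro-meso and
#' meso-meta); 2 adds pro-meta diagonal cross connections; 3 adds
#' bidirectional ipsilateral pro-meta connections; 4 adds a unidirectional
#' ipsilateral meta-to-pro connection.
#'
#' @param architecture_id Integer id within the model space.
#' @param n_segments 2 or 3.
#' @param segments Segment names, rostral first. Defaults to
#'   `c("meso", "meta")` or `c("pro", "meso", "meta")`.
#' @return `architecture_mask()`: a logical adjacency matrix (`[i, j]` = edge
#'   from node j to node i) with node labels as dimnames.
#' @export
architecture_mask <- function(architecture_id, n_segments = 2, segments = NULL) {
  segments <- default_segments(n_segments, segments)
  labels <- node_labels(segments)
  cls <- edge_classes(labels)
  n <- length(labels)
  mask <- matrix(FALSE, n, n, dimnames = list(labels, labels))
  if (n_segments == 2) {
    if (!architecture_id %in% 1:7) {
      abort("unknown architecture_id for a two-segment space: valid ids are 1-7")
    }
    use <- switch(architecture_id,
      `1` = c("intra", "inter", "diag"),
      `2` = c("intra", "inter"),
      `3` = c("intra", "diag"),
      `4` = "inter",
      `5` = "diag",
      `6` = "intra",
      `7` = character(0)
    )
    mask[] <- cls %in% use
  } else {
    if (!architecture_id %in% 1:4) {
      abort("unknown architecture_id for a three-segment space: valid ids are 1-4")
    }
    info <- channel_info(labels)
    seg <- info$segment
    adjacent <- abs(outer(match(seg, segments), match(seg, segments), "-")) == 1
    base <- (cls == "intra") | (cls == "inter" & adjacent)
    extra <- matrix(FALSE, n, n)
    pro <- seg == segments[1]
    meta <- seg == segments[3]
    if (architecture_id == 2) {
      extra <- cls == "diag" & (outer(pro, meta, "&") | outer(meta, pro, "&"))
    } else if (architecture_id == 3) {
      extra <- cls == "inter" & (outer(pro, meta, "&") | outer(meta, pro, "&"))
    } else if (architecture_id == 4) {
      extra <- cls == "inter" & outer(pro, meta, "&") # meta (col) -> pro (row)
    }
    mask[] <- base | extra
  }
  diag(mask) <- FALSE
  mask
}

default_segments <- function(n_segments, segments = NULL) {
  if (!is.null(segments)) {
    stopifnot(length(segments) == n_segments)
    return(segments)
  }
  if (n_segments == 2) c("meso", "meta") else c("pro", "meso", "meta")
}

node_labels <- function(segments) {
  as.vector(t(outer(segments, c("L", "R"), paste, sep = "_")))
}

# matrix of edge classes for an ordered label set; [i, j] classifies j -> i
edge_classes <- function(labels) {
  info <- channel_info(labels)
  same_seg <- outer(info$segment, info$segment, "==")
  same_side <- outer(info$side, info$side, "==")
  cls <- matrix("diag", length(labels), length(labels))
  cls[same_seg & !same_side] <- "intra"
  cls[!same_seg & same_side] <- "inter"
  cls[same_seg & same_side] <- "self"
  cls
}

#' Build a ground-truth coupled-oscillator network from an architecture
#'
#' Places coupling strengths on the edge set of one candidate architecture,
#' producing the ground truth that drives the synthetic burst generator. The
#' coupling matrix entry `[i, j]` is the influence of node j on node i;
#' the diagonal is zero and every nonzero entry carries the network's sign
#' (negative for inhibitory).
#'
#' @inheritParams architecture_mask
#' @param strengths Named list or vector with entries `intra`, `inter`,
#'   `diag` giving the strength per edge class (missing classes default to 0).
#' @param intrinsic_freqs Per-node cycle frequency in Hz, recycled to the
#'   number of nodes (default 0.2 Hz, i.e. ~5 s cycles).
#' @param sign `"excitatory"` or `"inhibitory"`.
#' @return A `cpg_network`: list with `labels`, `coupling`, `intrinsic_freqs`,
#'   `sign`, `architecture_id`.
#' @examples
#' net <- make_architecture_network(2, strengths = list(intra = 0.3, inter = 0.2))
#' sum(net$coupling != 0) # 8 directed edges
#' @export
make_architecture_network <- function(architecture_id, n_segments = 2,
                                      strengths = list(intra = 0.3, inter = 0.2, diag = 0.1),
                                      intrinsic_freqs = 0.2,
                                      sign = c("excitatory", "inhibitory"),
                                      segments = NULL) {
  sign <- match.arg(sign)
  mask <- architecture_mask(architecture_id, n_segments, segments)
  labels <- rownames(mask)
  cls <- edge_classes(labels)
  s <- function(k) if (is.null(strengths[[k]])) 0 else strengths[[k]]
  K <- matrix(0, nrow(mask), ncol(mask), dimnames = dimnames(mask))
  for (k in c("intra", "inter", "diag")) {
    K[mask & cls == k] <- s(k)
  }
  if (sign == "inhibitory") K <- -K
  new_network(labels, K, rep_len(intrinsic_freqs, length(labels)), sign,
              architecture_id)
}

new_network <- function(labels, coupling, intrinsic_freqs, sign,
                        architecture_id = NA) {
  stopifnot(
    nrow(coupling) == length(labels), ncol(coupling) == length(labels),
    all(diag(coupling) == 0), !anyDuplicated(labels)
  )
  nz <- coupling[coupling != 0]
  if (length(nz) > 0) {
    want <- if (sign == "inhibitory") -1 else 1
    if (any(base::sign(nz) != want)) {
      abort("all nonzero coupling entries must match the network sign")
    }
  }
  structure(
    list(labels = labels, coupling = coupling,
         intrinsic_freqs = setNames(intrinsic_freqs, labels), sign = sign,
         architecture_id = architecture_id),
    class = "cpg_network"
  )
}

#' @exportS3Method base::print
print.cpg_network <- function(x, ...) {
  cat(sprintf(
    "<cpg_network> %d nodes (%s), %d directed edges, %s, architecture %s\n",
    length(x$labels), paste(x$labels, collapse = ", "),
    sum(x$coupling != 0), x$sign, x$architecture_id
  ))
  invisible(x)
}

#' Segment membership of each node
#' @param network A `cpg_network`.
#' @return Character vector of segments, one per node.
#' @export
network_segments <- function(network) channel_info(network$labels)$segment
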