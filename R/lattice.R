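# 3x3x3 lattice expansion: symmetry-placed chain copies around the
# reference cell, and bounding-box pruning of candidate contact pairs.

#' Expand the crystal lattice around the asymmetric unit
#'
#' Builds one placement per (chain, symmetry operator, cell translation)
#' for the 27 unit cells of the 3x3x3 block centred on the reference
#' cell. Placements carry the composed orthogonal-frame affine map; the
#' identity placement (identity operator, zero shift) reproduces the
#' deposited coordinates exactly. Ordering is deterministic: chain (entry
#' order), then operator index, then shift lexicographic.
#'
#' @param entry a crystallographic `xc_entry`.
#' @return list of `xc_placement` objects.
#' @export
expand_lattice <- function(entry) {
  .assert_crystallographic(entry)
  M <- frac_to_orth_matrix(entry$cell)
  Mi <- solve(M)
  shifts <- expand.grid(sk = -1:1, sj = -1:1, si = -1:1)[, 3:1]
  shifts <- shifts[order(shifts$si, shifts$sj, shifts$sk), ]
  out <- vector("list", length(entry$chains) * length(entry$sym_ops) * 27L)
  idx <- 0L
  for (asym in names(entry$chains)) {
    for (k in seq_along(entry$sym_ops)) {
      op <- entry$sym_ops[[k]]
      for (s in seq_len(27L)) {
        sh <- as.integer(shifts[s, ])
        idx <- idx + 1L
        if (k == 1L && all(sh == 0L)) {
          R <- diag(3); t <- c(0, 0, 0)  # bit-equal identity
        } else {
          R <- M %*% op$R %*% Mi
          t <- as.vector(M %*% (op$t + sh))
        }
        out[[idx]] <- structure(
          list(asym_id = asym, op_index = k, shift = sh, R = R, t = t,
               placement_id = sprintf("%s.%d.%d%d%d", asym, k,
                                      sh[1L] + 1L, sh[2L] + 1L, sh[3L] + 1L)),
          class = "xc_placement")
      }
    }
  }
  out
}

#' Is a placement the identity copy?
#' @param p an `xc_placement`.
#' @return logical.
#' @export
is_identity_placement <- function(p) {
  p$op_index == 1L && all(p$shift == 0L)
}

# Transformed heavy-atom coordinates of a chain under a placement.
.placed_xyz <- function(xyz, placement) {
  if (is_identity_placement(placement)) return(as.matrix(xyz))
  apply_transform(xyz, placement$R, placement$t)
}

# Axis-aligned bounding box of a placed chain, conservative under
# rotation (box of the transformed corners of the base box).
.placement_box <- function(base_box, placement) {
  if (is_identity_placement(placement)) return(base_box)
  corners <- as.matrix(expand.grid(base_box[, 1L], base_box[, 2L],
                                   base_box[, 3L]))
  tc <- apply_transform(corners, placement$R, placement$t)
  rbind(apply(tc, 2L, min), apply(tc, 2L, max))
}

#' Prune placement pairs by bounding-box overlap
#'
#' Returns every (reference placement, lattice placement) index pair
#' whose axis-aligned bounding boxes, inflated by `prune_radius`,
#' overlap. This is a guaranteed superset of all pairs that can hold an
#' atomic or C-beta contact at cutoffs up to `prune_radius`.
#'
#' @param entry the `xc_entry` the placements came from.
#' @param placements full lattice from [expand_lattice()].
#' @param reference indices into `placements` of the reference units
#'   (default: the identity asymmetric-unit copies).
#' @param prune_radius inflation radius in Angstrom; must cover the
#'   contact cutoffs in use.
#' @return data.frame with columns `ref` and `other` (indices into
#'   `placements`), self-pairs excluded.
#' @export
candidate_pairs <- function(entry, placements,
                            reference = which(vapply(placements,
                                                     is_identity_placement,
                                                     logical(1L))),
                            prune_radius = pipeline_config()$prune_radius) {
  boxes_base <- lapply(entry$chains, function(ch) {
    xyz <- as.matrix(ch$atoms[, c("x", "y", "z")])
    rbind(apply(xyz, 2L, min), apply(xyz, 2L, max))
  })
  boxes <- lapply(placements, function(p) {
    .placement_box(boxes_base[[p$asym_id]], p)
  })
  lo <- t(vapply(boxes, function(b) b[1L, ], numeric(3L)))
  hi <- t(vapply(boxes, function(b) b[2L, ], numeric(3L)))
  out_ref <- integer(0); out_other <- integer(0)
  for (r in reference) {
    ok <- which(
      lo[, 1L] <= hi[r, 1L] + prune_radius &
      hi[, 1L] >= lo[r, 1L] - prune_radius &
      lo[, 2L] <= hi[r, 2L] + prune_radius &
      hi[, 2L] >= lo[r, 2L] - prune_radius &
      lo[, 3L] <= hi[r, 3L] + prune_radius &
      hi[, 3L] >= lo[r, 3L] - prune_radius)
    ok <- setdiff(ok, r)
    out_ref <- c(out_ref, rep.int(r, length(ok)))
    out_other <- c(out_other, ok)
  }
  data.frame(ref = out_ref, other = out_other)
}

#' Export an expanded lattice as a multi-model PDB file for inspection
#'
#' Debug aid: each placement becomes one MODEL with the source chain's
#' heavy atoms transformed into place.
#'
#' @param entry the entry.
#' @param placements placements to export.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
export_lattice_pdb <- function(entry, placements, path) {
  con <- file(path, "w")
  on.exit(close(con))
  for (m in seq_along(placements)) {
    p <- placements[[m]]
    ch <- entry$chains[[p$asym_id]]
    xyz <- .placed_xyz(as.matrix(ch$atoms[, c("x", "y", "z")]), p)
    cat(sprintf("MODEL %8d\n", m), file = con)
    for (i in seq_len(nrow(xyz))) {
      cat(sprintf("ATOM  %5d %-4s %3s %1s%4d    %8.3f%8.3f%8.3f  1.00  0.00          %2s\n",
                  i, substr(ch$atoms$atom[i], 1, 4),
                  substr(ch$atoms$resname[i], 1, 3),
                  substr(p$asym_id, 1, 1), ch$atoms$seq_pos[i],
                  xyz[i, 1L], xyz[i, 2L], xyz[i, 3L],
                  ch$atoms$element[i]),
          file = con)
    }
    cat("ENDMDL\n", file = con)
  }
  invisible(path)
}
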