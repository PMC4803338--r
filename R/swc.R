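# SWC writing/reading.  The model is a 1-D cable; 3-D coordinates are
# synthesized (straight sections, fixed branching angles) purely so the tree
# can be exchanged in the standard 7-column format.  Coordinates carry no
# physics; cable lengths and radii are exact.

# unit direction for each section, chosen per tree side with fixed fan-out
.swc_directions <- function(sections) {
  rot <- function(deg) {
    a <- deg * pi / 180
    c(sin(a), 0, cos(a))
  }
  dirs <- list(
    soma = c(0, 0, 1), axon = c(0.5, 0, -sqrt(0.75)),
    trunk_prox = c(0, 0, 1), trunk_dist = c(0, 0, 1),
    oblique = rot(55),
    tuft_a = rot(-25), tuft_b = rot(25),
    tuft_a_a = rot(-40), tuft_a_b = rot(-10),
    tuft_b_a = rot(10), tuft_b_b = rot(40),
    basal = c(0, 0, -1),
    basal_a = -rot(25), basal_b = -rot(-25),
    basal_a_a = -rot(40), basal_a_b = -rot(10),
    basal_b_a = -rot(-10), basal_b_b = -rot(-40)
  )
  miss <- setdiff(sections$name, names(dirs))
  for (nm in miss) dirs[[nm]] <- c(0, 0, 1)
  dirs
}

#' Export a morphology to SWC
#'
#' Writes standard 7-column SWC samples (id, type, x, y, z, radius, parent);
#' one sample per section endpoint plus the soma root sample (parent -1).
#' Coordinates are synthesized with a straight-line layout; radii and
#' inter-sample distances reproduce the cable dimensions exactly, so a
#' re-import recovers the same section lengths and path-distance matrix.
#'
#' @param morph A `pyr_morphology`.
#' @param file Optional path; if `NULL` the SWC lines are returned.
#' @return Character vector of SWC lines (invisibly, if `file` is given).
#' @export
export_swc <- function(morph, file = NULL) {
  stopifnot(inherits(morph, "pyr_morphology"))
  sections <- morph$sections
  dirs <- .swc_directions(sections)
  type_of <- function(kind)
    switch(kind, soma = 1L, axon = 2L, basal = 3L, 4L)
  # sample id per section (sample sits at the section's 1-end)
  sid <- stats::setNames(seq_len(nrow(sections)), sections$name)
  xyz <- matrix(NA_real_, nrow(sections), 3)
  rows <- character(nrow(sections))
  # soma sample at the origin
  for (i in seq_len(nrow(sections))) {
    s <- sections[i, ]
    if (is.na(s$parent)) {
      xyz[i, ] <- c(0, 0, 0)
    } else {
      pstart <- xyz[sid[s$parent], ]
      # parent sample marks the parent's 1-end; sections here attach at
      # x = 0 or 1 of the parent, and the soma is the origin point
      origin <- if (s$parent == "soma") c(0, 0, 0) else pstart
      xyz[i, ] <- origin + dirs[[s$name]] * s$L
    }
  }
  for (i in seq_len(nrow(sections))) {
    s <- sections[i, ]
    parent_id <- if (is.na(s$parent)) -1L else sid[s$parent]
    rows[i] <- sprintf("%d %d %.4f %.4f %.4f %.6f %d",
                       sid[s$name], type_of(s$kind),
                       xyz[i, 1], xyz[i, 2], xyz[i, 3],
                       s$diam / 2, parent_id)
  }
  out <- c("# SWC export (synthesized coordinates, exact cable dimensions)",
           sprintf("# columns: id type x y z radius parent; soma sample is the root point"),
           rows)
  if (!is.null(file)) {
    writeLines(out, file)
    return(invisible(out))
  }
  out
}

#' Read an SWC file written by [export_swc()]
#'
#' Reconstructs a `pyr_morphology`-compatible section tree from SWC samples:
#' each non-root sample becomes a cylindrical section running from its parent
#' sample to itself, with length equal to the euclidean inter-sample distance
#' and diameter twice the sample radius.  Passive parameters take the package
#' defaults.
#'
#' @param x Path to an SWC file or a character vector of SWC lines.
#' @return A `pyr_morphology`.
#' @export
read_swc <- function(x) {
  lines <- if (length(x) == 1 && file.exists(x)) readLines(x) else x
  lines <- trimws(lines)
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  f <- utils::read.table(text = lines,
                         col.names = c("id", "type", "x", "y", "z", "r", "parent"))
  if (sum(f$parent == -1) != 1) stop("SWC must have exactly one root sample")
  root <- f$id[f$parent == -1]
  if (f$type[f$id == root] != 1) stop("SWC root sample must be of soma type")
  nm <- function(id, type) {
    if (id == root) return("soma")
    paste0(switch(type + 1L, "", "soma", "axon", "basal", "apical", "n", "n", "apical"),
           "_", id)
  }
  defaults <- morphology_defaults()
  rows <- list()
  for (i in seq_len(nrow(f))) {
    r <- f[i, ]
    if (r$parent == -1) {
      rows[[i]] <- data.frame(name = "soma", parent = NA_character_,
                              parent_x = NA_real_, L = 2 * r$r, diam = 2 * r$r,
                              nseg = 1L, kind = "soma", order = 0L,
                              stringsAsFactors = FALSE)
    } else {
      p <- f[f$id == r$parent, ]
      L <- sqrt(sum((c(r$x, r$y, r$z) - c(p$x, p$y, p$z))^2))
      kind <- c("soma", "axon", "basal", "apical")[min(r$type, 4)]
      rows[[i]] <- data.frame(name = nm(r$id, r$type),
                              parent = nm(p$id, p$type),
                              parent_x = if (r$parent == root) 0 else 1,
                              L = L, diam = 2 * r$r,
                              nseg = max(1L, as.integer(round(L / 5))),
                              kind = kind, order = 1L, stringsAsFactors = FALSE)
    }
  }
  sections <- do.call(rbind, rows)
  morph <- structure(list(sections = sections,
                          passive = defaults[c("cm", "ra", "rm", "el")],
                          params = defaults),
                     class = "pyr_morphology")
  morph$segs <- .build_segments(morph)
  morph
}
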