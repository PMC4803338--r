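#' @useDynLib dendrogate, .registration = TRUE
#' @importFrom Rcpp sourceCpp
#' @keywords internal
"_PACKAGE"

#' Default geometric parameters of the simplified pyramidal morphology
#'
#' The simplified cell consists of an axon initial segment, a cylindrical
#' soma, an apical trunk of 500 um total length that is split at the oblique
#' junction (100 um from the soma) into a proximal and a distal compartment,
#' an oblique dendrite, two first-order apical tuft branches with two
#' second-order daughters each, and a basal tree (main shaft plus first- and
#' second-order branches).  Daughter branches have 2/3 of the diameter of
#' their mother branch.  Second-order branches exist to avoid sealed-end
#' boundary effects; they carry the same channel densities but host no probes
#' or synapses.
#'
#' @return Named list of the documented, overridable geometry parameters
#'   (lengths and diameters in um, `nseg_*` discretization counts).
#' @export
morphology_defaults <- function() {
  list(
    axon_diam = 2, axon_length = 3, axon_nseg = 1,
    soma_diam = 18.5, soma_length = 18.5, soma_nseg = 1,
    trunk_diam = 2,
    trunk_prox_length = 100, trunk_prox_nseg = 19,
    trunk_dist_length = 400, trunk_dist_nseg = 73,
    apical_branch_length = 300, apical_branch_nseg = 91,
    basal_diam = 1,
    basal_branch_length = 150, basal_branch_nseg = 91,
    daughter_ratio = 2 / 3,
    cm = 0.75,      # uF/cm^2
    ra = 150,       # Ohm cm
    rm = 40000,     # Ohm cm^2
    el = -70        # mV
  )
}

#' Build the simplified pyramidal neuron morphology
#'
#' Constructs the branched tree of cylindrical sections used throughout the
#' package: axon initial segment (2 um diameter, 3 um length), soma (diameter
#' and height 18.5 um), apical trunk split 100 um + 400 um at the oblique
#' junction, a 300 um oblique dendrite, apical tuft branches, and a basal tree
#' with 150 um branches.  Passive parameters default to Cm = 0.75 uF/cm^2,
#' Ra = 150 Ohm cm, Rm = 40000 Ohm cm^2, E_L = -70 mV.
#'
#' @param overrides Named list overriding parameters named in
#'   [morphology_defaults()].  Unknown names are an error.
#' @return An object of class `pyr_morphology`: list with elements
#'   `sections` (one row per cable section), `segs` (one row per
#'   discretization segment, in parent-before-child order) and `passive`.
#' @examples
#' m <- build_simplified_pyramidal()
#' subset(m$sections, name %in% c("trunk_prox", "trunk_dist"))
#' @export
build_simplified_pyramidal <- function(overrides = list()) {
  p <- morphology_defaults()
  if (length(overrides)) {
    bad <- setdiff(names(overrides), names(p))
    if (length(bad) || is.null(names(overrides)) || any(names(overrides) == ""))
      stop("unknown morphology parameter(s): ", paste(bad, collapse = ", "))
    p[names(overrides)] <- overrides
  }
  geom <- unlist(p[c("axon_diam", "axon_length", "soma_diam", "soma_length",
                     "trunk_diam", "trunk_prox_length", "trunk_dist_length",
                     "apical_branch_length", "basal_diam",
                     "basal_branch_length", "daughter_ratio")])
  if (any(geom <= 0)) stop("non-positive geometry parameter")

  r <- p$daughter_ratio
  sec <- function(name, parent, parent_x, L, diam, nseg, kind, order = 1L) {
    data.frame(name = name, parent = parent, parent_x = parent_x,
               L = L, diam = diam, nseg = as.integer(nseg), kind = kind,
               order = as.integer(order), stringsAsFactors = FALSE)
  }
  sections <- rbind(
    sec("soma", NA_character_, NA_real_, p$soma_length, p$soma_diam,
        p$soma_nseg, "soma", 0L),
    sec("axon", "soma", 0, p$axon_length, p$axon_diam, p$axon_nseg, "axon", 0L),
    sec("trunk_prox", "soma", 1, p$trunk_prox_length, p$trunk_diam,
        p$trunk_prox_nseg, "trunk", 0L),
    sec("trunk_dist", "trunk_prox", 1, p$trunk_dist_length, p$trunk_diam,
        p$trunk_dist_nseg, "trunk", 0L),
    sec("oblique", "trunk_prox", 1, p$apical_branch_length, p$trunk_diam * r,
        p$apical_branch_nseg, "oblique", 1L),
    sec("tuft_a", "trunk_dist", 1, p$apical_branch_length, p$trunk_diam * r,
        p$apical_branch_nseg, "tuft", 1L),
    sec("tuft_b", "trunk_dist", 1, p$apical_branch_length, p$trunk_diam * r,
        p$apical_branch_nseg, "tuft", 1L),
    sec("tuft_a_a", "tuft_a", 1, p$apical_branch_length, p$trunk_diam * r^2,
        p$apical_branch_nseg, "tuft", 2L),
    sec("tuft_a_b", "tuft_a", 1, p$apical_branch_length, p$trunk_diam * r^2,
        p$apical_branch_nseg, "tuft", 2L),
    sec("tuft_b_a", "tuft_b", 1, p$apical_branch_length, p$trunk_diam * r^2,
        p$apical_branch_nseg, "tuft", 2L),
    sec("tuft_b_b", "tuft_b", 1, p$apical_branch_length, p$trunk_diam * r^2,
        p$apical_branch_nseg, "tuft", 2L),
    sec("basal", "soma", 0, p$basal_branch_length, p$basal_diam,
        p$basal_branch_nseg, "basal", 0L),
    sec("basal_a", "basal", 1, p$basal_branch_length, p$basal_diam * r,
        p$basal_branch_nseg, "basal", 1L),
    sec("basal_b", "basal", 1, p$basal_branch_length, p$basal_diam * r,
        p$basal_branch_nseg, "basal", 1L),
    sec("basal_a_a", "basal_a", 1, p$basal_branch_length, p$basal_diam * r^2,
        p$basal_branch_nseg, "basal", 2L),
    sec("basal_a_b", "basal_a", 1, p$basal_branch_length, p$basal_diam * r^2,
        p$basal_branch_nseg, "basal", 2L),
    sec("basal_b_a", "basal_b", 1, p$basal_branch_length, p$basal_diam * r^2,
        p$basal_branch_nseg, "basal", 2L),
    sec("basal_b_b", "basal_b", 1, p$basal_branch_length, p$basal_diam * r^2,
        p$basal_branch_nseg, "basal", 2L)
  )

  morph <- structure(
    list(sections = sections,
         passive = list(cm = p$cm, ra = p$ra, rm = p$rm, el = p$el),
         params = p),
    class = "pyr_morphology")
  morph$segs <- .build_segments(morph)
  morph
}

# Path distance (um) of a section's 0-end from the soma node.  The soma is a
# point in the path metric: all of its children start at distance 0.
.section_start_dist <- function(sections) {
  start <- stats::setNames(rep(NA_real_, nrow(sections)), sections$name)
  start["soma"] <- 0
  repeat {
    todo <- which(is.na(start))
    if (!length(todo)) break
    progressed <- FALSE
    for (i in todo) {
      par <- sections$parent[i]
      if (!is.na(start[par])) {
        pl <- if (par == "soma") 0 else sections$L[sections$name == par]
        start[sections$name[i]] <- start[par] + sections$parent_x[i] * pl
        progressed <- TRUE
      }
    }
    if (!progressed) stop("morphology tree is not connected to the soma")
  }
  start
}

# One row per discretization segment, parent-before-child (Hines) order.
.build_segments <- function(morph) {
  sections <- morph$sections
  start <- .section_start_dist(sections)
  segs <- NULL
  # map from section name -> vector of global segment ids (1-based)
  ids <- list()
  next_id <- 1L
  rows <- list()
  for (i in seq_len(nrow(sections))) {
    s <- sections[i, ]
    n <- s$nseg
    id <- seq.int(next_id, length.out = n)
    ids[[s$name]] <- id
    next_id <- next_id + n
    lseg <- s$L / n
    centre <- (seq_len(n) - 0.5) * lseg
    dist <- if (s$name == "soma") rep(0, n) else start[s$name] + centre
    # parent segment: previous segment in the section; the first segment
    # attaches to the parent section's segment nearest the attachment point
    parent_seg <- c(NA_integer_, id[-n])
    if (!is.na(s$parent)) {
      psec <- sections[sections$name == s$parent, ]
      pids <- ids[[s$parent]]
      k <- pmin(pmax(ceiling(s$parent_x * psec$nseg), 1L), psec$nseg)
      parent_seg[1] <- pids[k]
    }
    rows[[i]] <- data.frame(
      seg_id = id, section = s$name, kind = s$kind, order = s$order,
      i_in_sec = seq_len(n), x = (seq_len(n) - 0.5) / n,
      L_um = lseg, diam_um = s$diam, dist_um = dist,
      parent_seg = parent_seg, stringsAsFactors = FALSE)
  }
  segs <- do.call(rbind, rows)
  segs$area_cm2 <- pi * (segs$diam_um * 1e-4) * (segs$L_um * 1e-4)
  rownames(segs) <- NULL
  segs
}

#' Create a site address on the morphology
#'
#' A site is either a named section plus a fractional position, or a path
#' distance in um from the soma resolved along one of the standard routes
#' (`"apical"`: trunk and then the first tuft branch; `"basal"`: main shaft
#' and then the first basal daughter; `"oblique"`: trunk to the junction, then
#' the oblique dendrite).
#'
#' @param section Section name (e.g. `"trunk_prox"`).
#' @param x Fractional position in `[0, 1]` along the section.
#' @return A `site_address` object.
#' @examples
#' site("oblique", 0.5)
#' site_um(90, "apical")
#' @export
site <- function(section, x = 0.5) {
  stopifnot(is.character(section), length(section) == 1,
            is.numeric(x), length(x) == 1, x >= 0, x <= 1)
  structure(list(section = section, x = x), class = "site_address")
}

#' @rdname site
#' @param dist_um Path distance from the soma in um.
#' @param path One of `"apical"`, `"basal"`, `"oblique"`.
#' @export
site_um <- function(dist_um, path = c("apical", "basal", "oblique")) {
  path <- match.arg(path)
  stopifnot(is.numeric(dist_um), length(dist_um) == 1, dist_um >= 0)
  structure(list(dist_um = dist_um, path = path), class = "site_address")
}

# Standard routes used to resolve um-from-soma addresses.
.route_sections <- function(path) {
  switch(path,
         apical = c("trunk_prox", "trunk_dist", "tuft_a"),
         basal = c("basal", "basal_a"),
         oblique = c("trunk_prox", "oblique"),
         stop("unknown path: ", path))
}

#' Resolve a site address to a segment of the morphology
#'
#' @param morph A `pyr_morphology`.
#' @param s A `site_address` from [site()] or [site_um()].
#' @return One row of `morph$segs` (the segment whose centre is nearest the
#'   requested point).
#' @export
resolve_site <- function(morph, s) {
  stopifnot(inherits(morph, "pyr_morphology"), inherits(s, "site_address"))
  segs <- morph$segs
  if (!is.null(s$section)) {
    if (!s$section %in% morph$sections$name)
      stop("unknown section: ", s$section)
    cand <- segs[segs$section == s$section, ]
    cand[which.min(abs(cand$x - s$x)), ]
  } else {
    route <- .route_sections(s$path)
    cand <- segs[segs$section %in% route, ]
    maxd <- max(cand$dist_um + cand$L_um / 2)
    if (s$dist_um > maxd)
      stop("address ", s$dist_um, " um exceeds the ", s$path, " route (",
           round(maxd, 1), " um)")
    cand[which.min(abs(cand$dist_um - s$dist_um)), ]
  }
}

# Exact point description (section, um-along-section) for path_distance().
.resolve_point <- function(morph, s) {
  if (inherits(s, "site_address")) {
    if (!is.null(s$section)) {
      i <- match(s$section, morph$sections$name)
      if (is.na(i)) stop("unknown section: ", s$section)
      return(list(section = s$section,
                  along = s$x * morph$sections$L[i]))
    }
    route <- .route_sections(s$path)
    start <- .section_start_dist(morph$sections)
    for (nm in route) {
      L <- morph$sections$L[morph$sections$name == nm]
      if (s$dist_um <= start[nm] + L + 1e-9)
        return(list(section = nm, along = max(0, s$dist_um - start[nm])))
    }
    stop("address ", s$dist_um, " um exceeds the ", s$path, " route")
  }
  stop("not a site_address")
}

#' Path distance between two points on the morphology
#'
#' Length in um of the unique tree path between two resolved points.  The
#' soma acts as a point (zero length) in this metric, so a site 90 um up the
#' apical trunk is 90 um from the soma centre.
#'
#' @param morph A `pyr_morphology`.
#' @param a,b `site_address` objects.
#' @return Distance in um.
#' @examples
#' m <- build_simplified_pyramidal()
#' path_distance(m, site("soma", 0.5), site("trunk_prox", 1)) # 100
#' @export
path_distance <- function(morph, a, b) {
  pa <- .resolve_point(morph, a)
  pb <- .resolve_point(morph, b)
  sections <- morph$sections
  start <- .section_start_dist(sections)
  # chain of sections from root to the point's section
  chain <- function(sec) {
    out <- sec
    while (!is.na(sections$parent[match(out[1], sections$name)]))
      out <- c(sections$parent[match(out[1], sections$name)], out)
    out
  }
  # soma is a point: position along soma does not count
  along <- function(p) if (p$section == "soma") 0 else p$along
  ca <- chain(pa$section); cb <- chain(pb$section)
  ncom <- 0L
  while (ncom < min(length(ca), length(cb)) && ca[ncom + 1] == cb[ncom + 1])
    ncom <- ncom + 1L
  com <- ca[ncom]                     # deepest common section
  Lcom <- if (com == "soma") 0 else sections$L[match(com, sections$name)]
  # departure position (um along com) and residual distance for each point
  depart <- function(ch, p) {
    if (p$section == com) {
      list(y = along(p), r = 0)
    } else {
      nxt <- ch[ncom + 1]             # child of com on the way to p
      y <- sections$parent_x[match(nxt, sections$name)] * Lcom
      # residual: distance from the attachment point down to p
      r <- (start[p$section] + along(p)) - start[nxt]
      list(y = y, r = r)
    }
  }
  da <- depart(ca, pa); db <- depart(cb, pb)
  unname(abs(da$y - db$y) + da$r + db$r)
}
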