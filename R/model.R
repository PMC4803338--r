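# Assembly of a runnable neuron model: morphology + channel densities +
# kinetics, flattened into the per-segment arrays the compiled integrator
# consumes.  The settled resting state is computed lazily per time step and
# cached on the model object.

#' Assemble a simulatable pyramidal neuron model
#'
#' Combines a morphology, a channel density map and a set of kinetic
#' parameters into the flat per-segment arrays used by the integrator.
#'
#' @param morph A `pyr_morphology`; default [build_simplified_pyramidal()].
#' @param channels Channel parameter overrides passed to
#'   [assemble_channel_distribution()] (e.g. `list(gna_dend = 0)`).
#' @param kinetics Named overrides of [kinetics_defaults()].
#' @param passive_only If `TRUE`, all active conductances are zeroed and the
#'   model is exactly the passive cable (used as an analytic oracle).
#' @return A `pyr_model` object.
#' @examples
#' m <- build_neuron_model()
#' nrow(m$morph$segs)
#' @export
build_neuron_model <- function(morph = build_simplified_pyramidal(),
                               channels = list(),
                               kinetics = list(),
                               passive_only = FALSE) {
  if (passive_only) {
    channels <- utils::modifyList(
      list(gna_dend = 0, gkdr_dend = 0, gka0 = 0, gcah = 0, gkca = 0,
           gcal_zone = 0, gna_axon_total = 0),
      channels)
  }
  dens <- assemble_channel_distribution(morph, channels)
  kin <- kinetics_defaults()
  bad <- setdiff(names(kinetics), names(kin))
  if (length(bad)) stop("unknown kinetic parameter(s): ", paste(bad, collapse = ", "))
  kin[names(kinetics)] <- kinetics

  segs <- morph$segs
  n <- nrow(segs)
  pas <- morph$passive
  area <- segs$area_cm2
  # soma: cylinder side wall area (pi * d * L), consistent with all sections

  # axial coupling to the parent segment, uS
  half_res_Mohm <- function(i) {
    # MOhm from the segment centre to its end
    pas$ra * (segs$L_um[i] / 2 * 1e-4) /
      (pi * (segs$diam_um[i] / 2 * 1e-4)^2) / 1e6
  }
  hr <- vapply(seq_len(n), half_res_Mohm, numeric(1))
  g_ax <- numeric(n)
  parent <- segs$parent_seg
  for (i in seq_len(n)) {
    if (!is.na(parent[i])) g_ax[i] <- 1 / (hr[i] + hr[parent[i]])
  }

  cpp <- list(
    parent = as.integer(ifelse(is.na(parent), -1L, parent - 1L)),
    cm_nf = pas$cm * area * 1e3,
    g_ax = g_ax,
    area_cm2 = area,
    gna_uS = dens$gna * area * 1e6,
    gna2_uS = dens$gna2 * area * 1e6,
    na_shift = dens$na_shift,
    na2_shift = dens$na2_shift,
    gkdr_uS = dens$gkdr * area * 1e6,
    gka_uS = dens$gka * area * 1e6,
    gcah_uS = dens$gcah * area * 1e6,
    gcal_uS = dens$gcal * area * 1e6,
    gkca_uS = dens$gkca * area * 1e6,
    gleak_uS = area * 1e6 / pas$rm,
    el = pas$el,
    kin = kin)

  structure(list(morph = morph, densities = dens, kin = kin, cpp = cpp,
                 cache = new.env(parent = emptyenv())),
            class = "pyr_model")
}

#' @export
print.pyr_model <- function(x, ...) {
  cat("<pyr_model>", nrow(x$morph$segs), "segments,",
      nrow(x$morph$sections), "sections\n")
  invisible(x)
}

# segment index (1-based) for a site address
.seg_index <- function(model, s) resolve_site(model$morph, s)$seg_id

# settled resting state for a given dt (cached)
.settled_state <- function(model, dt, settle_ms, v_init = -70) {
  key <- sprintf("settled_dt%g_t%g_v%g", dt, settle_ms, v_init)
  st <- model$cache[[key]]
  if (is.null(st)) {
    res <- .engine_run(model$cpp,
                       list(steps = matrix(numeric(0), 0, 4),
                            synapses = list(), interneuron = NULL),
                       list(dt = dt, duration = settle_ms, v_init = v_init,
                            probe_seg = integer(0), probe_qty = integer(0)),
                       NULL)
    st <- res$state
    model$cache[[key]] <- st
  }
  st
}
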