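#' Scale counted cells to an areal density
#'
#' Converts a cell count over a counted area (typically about 10^3 um^2 of
#' an electron micrograph) to cells per square millimetre.
#'
#' @param count nonnegative cell count; vectorized.
#' @param counted_area counted area (um^2), `> 0`.
#' @return density (cells mm^-2).
#' @export
scale_cell_counts <- function(count, counted_area) {
  if (any(counted_area <= 0)) stop_se("'counted_area' must be > 0")
  if (any(count < 0)) stop_se("'count' must be >= 0")
  count * 1e6 / counted_area
}

#' Default surface x assay effect table
#'
#' Plausible graded bioadhesion means for a panel of sterol-analogue SCLs
#' plus the bare reference substrates, spanning two bacterial-adhesion
#' assays (relative adherent cell densities) and three protein-adsorption
#' assays (relative adsorbed masses). Values are generator inputs, not
#' measured data.
#'
#' @return data frame `surface, assay, mean`.
#' @export
default_assay_effects <- function() {
  surfaces <- c("cholesterol_scl", "dehydrocholesterol_scl",
                "stigmasterol_scl", "cholestanol_scl", "SiO2", "gold")
  assays <- c("ecoli_adhesion", "sepidermidis_adhesion",
              "bsa_adsorption", "lysozyme_adsorption", "fbs_adsorption")
  ## rows: surfaces in the order above; columns: assays
  m <- rbind(c(1.0, 1.0, 1.0, 1.0, 1.0),
             c(1.3, 1.4, 1.2, 1.3, 1.2),
             c(2.5, 2.8, 2.2, 2.4, 2.3),
             c(3.2, 3.0, 2.8, 3.1, 2.9),
             c(4.5, 4.8, 4.0, 4.2, 4.4),
             c(4.0, 4.2, 4.6, 4.4, 4.3))
  data.frame(surface = rep(surfaces, times = length(assays)),
             assay = rep(assays, each = length(surfaces)),
             mean = as.vector(m), stringsAsFactors = FALSE)
}

#' Generate a replicate-level multi-assay adhesion table
#'
#' Draws replicate values around the configured surface x assay means with
#' relative Gaussian noise.
#'
#' @param effects data frame `surface, assay, mean` (default
#'   [default_assay_effects()]).
#' @param noise_cv relative noise coefficient of variation.
#' @param replicates replicates per surface x assay cell.
#' @param reference_surfaces surfaces that must be present (the index
#'   reference and the assay controls).
#' @param seed RNG seed.
#' @return data frame `surface, assay, replicate, value`.
#' @export
gen_assay_table <- function(effects = default_assay_effects(),
                            noise_cv = 0.1, replicates = 6L,
                            reference_surfaces = c("cholesterol_scl",
                                                   "SiO2", "gold"),
                            seed = 11L) {
  if (!nrow(effects)) stop_se("'effects' is empty")
  missing <- setdiff(reference_surfaces, effects$surface)
  if (length(missing))
    stop_se("missing reference surface(s): ", paste(missing, collapse = ", "))
  with_seed(seed, {
    out <- do.call(rbind, lapply(seq_len(nrow(effects)), function(i) {
      v <- effects$mean[i] *
        (1 + if (noise_cv > 0) stats::rnorm(replicates, 0, noise_cv) else 0)
      data.frame(surface = effects$surface[i], assay = effects$assay[i],
                 replicate = seq_len(replicates), value = pmax(v, 0),
                 stringsAsFactors = FALSE)
    }))
    out
  })
}

#' Normalize assay results to a reference surface
#'
#' Per assay, divides each surface's summary statistic (mean by default,
#' median optionally) by the reference surface's statistic for that assay.
#'
#' @param table data frame `surface, assay, value`.
#' @param reference_surface surface to normalize to.
#' @param stat `"mean"` (default) or `"median"`.
#' @return data frame `surface, assay, value_norm`.
#' @export
normalize_assays <- function(table, reference_surface = "cholesterol_scl",
                             stat = c("mean", "median")) {
  stat <- match.arg(stat)
  f <- if (stat == "mean") mean else stats::median
  agg <- stats::aggregate(value ~ surface + assay, data = table, FUN = f)
  out <- do.call(rbind, lapply(unique(agg$assay), function(a) {
    sub <- agg[agg$assay == a, ]
    ref <- sub$value[sub$surface == reference_surface]
    if (!length(ref)) stop_se("reference surface '", reference_surface,
                              "' missing in assay '", a, "'")
    if (ref == 0) stop_se("zero reference ", stat, " in assay '", a, "'")
    data.frame(surface = sub$surface, assay = a,
               value_norm = sub$value / ref, stringsAsFactors = FALSE)
  }))
  rownames(out) <- NULL
  out
}

#' Aggregate normalized assays into a bioadhesion index
#'
#' Per surface, the index is the arithmetic mean (optionally geometric) of
#' its normalized assay components; the reference SCL surface therefore has
#' index 1 exactly. A separate reference value is computed the same way
#' from the control substrates of each assay class (bare SiO2 for the
#' bacterial assays, bare gold for the protein assays).
#'
#' @param normalized data frame from [normalize_assays()].
#' @param aggregate `"mean"` (default) or `"geometric"`.
#' @param controls named character vector mapping assay class to its
#'   control surface.
#' @param assay_classes named character vector mapping each assay to
#'   `"bacterial"` or `"protein"`; defaults cover the standard five-assay
#'   panel.
#' @return a `bioadhesion_index` list: `index` (data frame
#'   `surface, index`), `components` (the normalized table),
#'   `reference_value`, `aggregate`.
#' @export
bioadhesion_index <- function(normalized, aggregate = c("mean", "geometric"),
                              controls = c(bacterial = "SiO2",
                                           protein = "gold"),
                              assay_classes = c(
                                ecoli_adhesion = "bacterial",
                                sepidermidis_adhesion = "bacterial",
                                bsa_adsorption = "protein",
                                lysozyme_adsorption = "protein",
                                fbs_adsorption = "protein")) {
  aggregate <- match.arg(aggregate)
  assays <- unique(normalized$assay)
  surfaces <- unique(normalized$surface)
  for (s in surfaces) {
    have <- normalized$assay[normalized$surface == s]
    miss <- setdiff(assays, have)
    if (length(miss))
      stop_se("surface '", s, "' is missing assay(s): ",
              paste(miss, collapse = ", "))
  }
  agg_fun <- if (aggregate == "mean") mean else function(v) exp(mean(log(v)))
  idx <- vapply(surfaces, function(s)
    agg_fun(normalized$value_norm[normalized$surface == s]), 0)
  ## reference value: each assay contributes its own control substrate
  ref_parts <- vapply(assays, function(a) {
    cls <- assay_classes[[a]] %||% "protein"
    ctrl <- controls[[cls]]
    v <- normalized$value_norm[normalized$assay == a &
                                 normalized$surface == ctrl]
    if (!length(v)) NA_real_ else v
  }, 0)
  structure(list(index = data.frame(surface = surfaces, index = unname(idx),
                                    stringsAsFactors = FALSE),
                 components = normalized,
                 reference_value = if (all(is.na(ref_parts))) NA_real_
                 else agg_fun(ref_parts[!is.na(ref_parts)]),
                 aggregate = aggregate),
            class = "bioadhesion_index")
}

#' @export
print.bioadhesion_index <- function(x, ...) {
  cat("bioadhesion index (", x$aggregate, " aggregation):\n", sep = "")
  print(x$index, row.names = FALSE)
  cat(sprintf("reference value (bare-substrate controls): %.3f\n",
              x$reference_value))
  invisible(x)
}
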