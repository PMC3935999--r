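# Combined 1H/15N amide chemical-shift perturbations from free/bound peak
# lists, three-bin classification, and per-region summaries.

#' Combined amide chemical-shift perturbation
#'
#' `dd_HN = sqrt( (ddH)^2 + (n_scale * ddN)^2 )` with `ddX = bound - free`.
#' The 15N scale factor defaults to 1/5 (the dominant convention for
#' backbone amides); 0.14 is a common alternative and can be supplied
#' instead.
#'
#' @param dH_free,dN_free,dH_bound,dN_bound Chemical shifts, ppm
#'   (vectorized).
#' @param n_scale 15N scaling factor (default 0.2).
#' @return Combined perturbation(s), ppm, always >= 0.
#' @examples
#' combined_csp(8.0, 120, 8.3, 121)   # sqrt(0.09 + 0.04) = 0.3606
#' @export
combined_csp <- function(dH_free, dN_free, dH_bound, dN_bound,
                         n_scale = 0.2) {
  v <- c(dH_free, dN_free, dH_bound, dN_bound)
  if (!all(is.finite(v))) stop("non-finite chemical shift")
  sqrt((dH_bound - dH_free)^2 + (n_scale * (dN_bound - dN_free))^2)
}

#' Construct a peak list
#'
#' @param resi Integer residue indices (protein numbering); at most one
#'   peak per residue.
#' @param dH,dN 1H and 15N shifts, ppm.
#' @param label Free text (`"free"`, `"bound"`, or a titration point tag).
#' @param ligand_conc Optional ligand concentration, M.
#' @return Object of class `peak_list` (a data.frame with attributes).
#' @export
peak_list <- function(resi, dH, dN, label = "", ligand_conc = NULL) {
  resi <- as.integer(resi)
  if (anyDuplicated(resi)) stop("duplicate residue in peak list")
  if (!all(is.finite(dH)) || !all(is.finite(dN))) {
    stop("non-finite chemical shift")
  }
  out <- data.frame(resi = resi, dH = dH, dN = dN)
  attr(out, "label") <- label
  attr(out, "ligand_conc") <- ligand_conc
  class(out) <- c("peak_list", "data.frame")
  out
}

#' Per-residue perturbation profile between two peak lists
#'
#' Residues present in only one list are reported in `unmatched`, never
#' silently dropped.
#'
#' @param free,bound [peak_list()]s sharing at least one residue.
#' @param n_scale 15N scaling factor.
#' @return Object of class `csp_profile`: data.frame with `resi` and
#'   `csp` (ppm), attribute `unmatched` (integer residue indices).
#' @export
perturbation_profile <- function(free, bound, n_scale = 0.2) {
  shared <- intersect(free$resi, bound$resi)
  if (length(shared) == 0) stop("peak lists share no residues")
  f <- free[match(shared, free$resi), ]
  b <- bound[match(shared, bound$resi), ]
  out <- data.frame(resi = shared,
                    csp = combined_csp(f$dH, f$dN, b$dH, b$dN, n_scale))
  out <- out[order(out$resi), ]
  rownames(out) <- NULL
  attr(out, "unmatched") <- sort(c(setdiff(free$resi, shared),
                                   setdiff(bound$resi, shared)))
  class(out) <- c("csp_profile", "data.frame")
  out
}

#' Classify a perturbation into the three standard bins
#'
#' Bins partition `[0, Inf)`: low = `[0, 0.2)`, medium = `[0.2, 0.5)`,
#' high = `[0.5, Inf)` ppm; boundary values go to the upper bin. These
#' match the conventional blue/yellow/red colour code for structure
#' mapping.
#'
#' @param value Perturbation(s), ppm, >= 0.
#' @return Factor with levels `low`, `medium`, `high`.
#' @export
classify_csp <- function(value) {
  if (any(value < 0)) stop("perturbations must be >= 0")
  cut(value, breaks = c(0, 0.2, 0.5, Inf), labels = c("low", "medium",
                                                      "high"),
      right = FALSE, include.lowest = TRUE)
}

#' Secondary-structure region map for PSD-95 PDZ3
#'
#' Only the beta2-beta3 loop (329-334) and the C-terminal alpha-3 helix
#' (394-403, the domain's last ten residues) are pinned by the study; the
#' remaining ranges are conventional approximations and overridable.
#'
#' @param ... Named integer vectors overriding or adding regions.
#' @return Named list of integer residue-index vectors, all within
#'   302..403.
#' @export
default_region_map <- function(...) {
  regions <- list(
    b2_strand = 323:328,
    b2b3_loop = 329:334,
    b3_strand = 336:341,
    a2_helix = 369:378,
    a3_helix = 394:403
  )
  over <- list(...)
  regions[names(over)] <- over
  bad <- vapply(regions, function(r) any(r < 302 | r > 403), FALSE)
  if (any(bad)) stop("region indices outside 302..403: ",
                     paste(names(regions)[bad], collapse = ", "))
  regions
}

#' Per-region summary of a perturbation profile
#'
#' @param profile A [perturbation_profile()].
#' @param regions Named list of residue-index vectors
#'   ([default_region_map()] by default).
#' @return `data.frame` with one row per region: `region`, `n` (residues
#'   with data), `n_medium`, `n_high`, `max_csp`, `mean_csp`. Regions
#'   with no observed residues give a zero-count row with a warning.
#' @export
region_summary <- function(profile, regions = default_region_map()) {
  bins <- classify_csp(profile$csp)
  rows <- lapply(names(regions), function(nm) {
    sel <- profile$resi %in% regions[[nm]]
    if (!any(sel)) {
      warning("region ", nm, " has no observed residues")
      return(data.frame(region = nm, n = 0L, n_medium = 0L, n_high = 0L,
                        max_csp = 0, mean_csp = 0))
    }
    data.frame(region = nm, n = sum(sel),
               n_medium = sum(bins[sel] == "medium"),
               n_high = sum(bins[sel] == "high"),
               max_csp = max(profile$csp[sel]),
               mean_csp = mean(profile$csp[sel]))
  })
  do.call(rbind, rows)
}

#' Read / write tab-delimited peak lists
#'
#' Columns: `resi`, `dH_ppm`, `dN_ppm`.
#'
#' @param path File path.
#' @return A [peak_list()].
#' @export
read_peak_list <- function(path) {
  df <- utils::read.delim(path)
  peak_list(df$resi, df$dH_ppm, df$dN_ppm)
}

#' @rdname read_peak_list
#' @param peaks A [peak_list()] to serialize.
#' @export
write_peak_list <- function(peaks, path) {
  utils::write.table(data.frame(resi = peaks$resi, dH_ppm = peaks$dH,
                                dN_ppm = peaks$dN),
                     path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Annotate a profile with bins and colour codes
#'
#' @param profile A [perturbation_profile()].
#' @return data.frame with `resi`, `csp`, `bin` and the conventional
#'   mapping colour (`blue`/`yellow`/`red`).
#' @export
profile_with_bins <- function(profile) {
  bins <- classify_csp(profile$csp)
  data.frame(resi = profile$resi, csp = profile$csp, bin = bins,
             colour = c(low = "blue", medium = "yellow",
                        high = "red")[as.character(bins)],
             row.names = NULL)
}
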