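#' Build a conformational state model
#'
#' A state model describes one receptor subtype x probe site x ligand
#' condition as a small set of FRET states: each state has an ideal mean
#' FRET efficiency, a width (the FRET standard deviation contributed by
#' conformational motion too fast to resolve at the 10 frames/s acquisition
#' rate), an equilibrium occupancy, and a mean dwell time in frames.
#'
#' @param subtype GluN2 subunit identity (e.g. `"GluN2A"`) or a chimera id.
#' @param probe_site `"NTD-W56"` or `"LBD-D677"` (GluN1 labeling site).
#' @param ligand_condition One of `"apo_like"`, `"glycine_only"`,
#'   `"glutamate_only"`, `"full_agonist"`.
#' @param mean_fret Numeric vector of state mean FRET efficiencies in
#'   \[0, 1\].
#' @param occupancies Equilibrium occupancy of each state; must sum to 1.
#' @param width State-level FRET s.d. per state (recycled); default 0.05.
#' @param mean_dwell_frames Mean dwell time per state in frames (recycled);
#'   must be >= 1. Default 20 frames (2 s at 10 frames/s).
#' @param label Optional state labels.
#' @return An object of class `state_model`.
#' @export
state_model <- function(subtype, probe_site, ligand_condition,
                        mean_fret, occupancies,
                        width = 0.05, mean_dwell_frames = 20,
                        label = NULL) {
  k <- length(mean_fret)
  if (k < 1L) abort_smfret("a state model needs at least one state")
  if (any(mean_fret < 0 | mean_fret > 1))
    abort_smfret("state mean FRET must lie in [0, 1]")
  width <- rep_len(width, k)
  if (any(width <= 0)) abort_smfret("state widths must be positive")
  mean_dwell_frames <- rep_len(mean_dwell_frames, k)
  if (any(mean_dwell_frames < 1))
    abort_smfret("mean dwell times must be >= 1 frame")
  if (length(occupancies) != k)
    abort_smfret("`occupancies` must have one weight per state")
  if (any(occupancies < 0) || abs(sum(occupancies) - 1) > 1e-9)
    abort_smfret("`occupancies` must be non-negative and sum to 1 (within 1e-9)")
  if (is.null(label)) label <- sprintf("E%.2f", mean_fret)
  structure(
    list(subtype = subtype, probe_site = probe_site,
         ligand_condition = ligand_condition,
         states = tibble::tibble(label = label, mean_fret = mean_fret,
                                 width = width,
                                 mean_dwell_frames = mean_dwell_frames),
         occupancies = occupancies),
    class = "state_model")
}

#' @export
print.state_model <- function(x, ...) {
  cat(sprintf("<state_model> %s / %s / %s\n",
              x$subtype, x$probe_site, x$ligand_condition))
  df <- x$states
  df$occupancy <- x$occupancies
  print(as.data.frame(df), row.names = FALSE)
  invisible(x)
}

# The packaged library of subtype x probe-site x ligand-condition models.
#
# Peak positions come from the published smFRET distributions; the texts
# describe occupancies only qualitatively (major / minor / small tail), so
# the packaged weights follow an 0.80/0.20 major/minor convention (1.0 for
# single-peak conditions) except where noted per entry. Widths default to
# 0.05 FRET units; "broad" peaks carry larger widths.
condition_library <- function() {
  m <- function(...) state_model(...)
  list(
    # --- GluN1 lower-LBD probe (D677), apo-like (CGP, no agonists) ---
    m("GluN2A", "LBD-D677", "apo_like",
      mean_fret = c(0.35, 0.70), occupancies = c(0.85, 0.15),
      label = c("separated", "high tail")),
    m("GluN2B", "LBD-D677", "apo_like",
      mean_fret = 0.35, occupancies = 1, label = "separated"),
    m("GluN2C", "LBD-D677", "apo_like",
      mean_fret = c(0.35, 0.70), occupancies = c(0.75, 0.25),
      label = c("separated", "proximal")),
    m("GluN2D", "LBD-D677", "apo_like",
      mean_fret = 0.48, occupancies = 1, width = 0.10, label = "broad"),
    # --- LBD, fully agonized (glycine + glutamate): convergent ~0.25 peak ---
    m("GluN2A", "LBD-D677", "full_agonist", 0.25, 1, label = "agonized"),
    m("GluN2B", "LBD-D677", "full_agonist", 0.25, 1, label = "agonized"),
    m("GluN2C", "LBD-D677", "full_agonist", 0.25, 1, label = "agonized"),
    m("GluN2D", "LBD-D677", "full_agonist", 0.25, 1, label = "agonized"),
    # --- LBD, single agonists: glycine shifts low more than glutamate ---
    m("GluN2A", "LBD-D677", "glycine_only", 0.27, 1),
    m("GluN2B", "LBD-D677", "glycine_only", 0.27, 1),
    m("GluN2C", "LBD-D677", "glycine_only", 0.27, 1),
    m("GluN2D", "LBD-D677", "glycine_only", 0.27, 1),
    m("GluN2A", "LBD-D677", "glutamate_only", 0.32, 1),
    m("GluN2B", "LBD-D677", "glutamate_only", 0.32, 1),
    m("GluN2C", "LBD-D677", "glutamate_only", 0.32, 1),
    m("GluN2D", "LBD-D677", "glutamate_only",
      mean_fret = c(0.35, 0.55), occupancies = c(0.60, 0.40), width = 0.08,
      label = c("low", "high")),
    # --- GluN1 NTD probe (W56), apo-like: subtype-specific splaying.
    # GluN2C departs from the 0.80/0.20 convention: its low-FRET (splayed)
    # peak is described as larger but with a substantial broad compact peak,
    # and its splayed occupancy sits strictly between GluN2A/B and GluN2D.
    m("GluN2A", "NTD-W56", "apo_like",
      mean_fret = c(0.20, 0.60), occupancies = c(0.20, 0.80),
      label = c("splayed", "compact")),
    m("GluN2B", "NTD-W56", "apo_like",
      mean_fret = c(0.20, 0.50), occupancies = c(0.20, 0.80),
      label = c("splayed", "compact")),
    m("GluN2C", "NTD-W56", "apo_like",
      mean_fret = c(0.20, 0.56), occupancies = c(0.60, 0.40),
      width = c(0.05, 0.08), label = c("splayed", "compact")),
    m("GluN2D", "NTD-W56", "apo_like",
      mean_fret = c(0.18, 0.60), occupancies = c(0.80, 0.20),
      label = c("splayed", "compact")),
    # --- NTD, fully agonized: subtype-specific compact peaks ---
    m("GluN2A", "NTD-W56", "full_agonist", 0.60, 1, label = "compact"),
    m("GluN2B", "NTD-W56", "full_agonist", 0.38, 1, width = 0.08,
      label = "compact"),
    m("GluN2C", "NTD-W56", "full_agonist",
      mean_fret = c(0.35, 0.62), occupancies = c(0.15, 0.85),
      label = c("splayed", "compact")),
    m("GluN2D", "NTD-W56", "full_agonist",
      mean_fret = c(0.40, 0.70), occupancies = c(0.15, 0.85),
      label = c("splayed", "compact")),
    # --- NTD, glycine only: drives the subtype-specific compact state ---
    m("GluN2A", "NTD-W56", "glycine_only", 0.60, 1, label = "compact"),
    m("GluN2B", "NTD-W56", "glycine_only", 0.38, 1, width = 0.08,
      label = "compact"),
    m("GluN2C", "NTD-W56", "glycine_only", 0.62, 1, label = "compact"),
    m("GluN2D", "NTD-W56", "glycine_only", 0.70, 1, label = "compact"),
    # --- NTD, glutamate only: opposite sign of shift in 2A/2B vs 2C/2D ---
    m("GluN2A", "NTD-W56", "glutamate_only",
      mean_fret = c(0.20, 0.60), occupancies = c(0.50, 0.50),
      label = c("splayed", "compact")),
    m("GluN2B", "NTD-W56", "glutamate_only", 0.30, 1,
      label = "intermediate"),
    m("GluN2C", "NTD-W56", "glutamate_only",
      mean_fret = c(0.20, 0.62), occupancies = c(0.40, 0.60),
      label = c("splayed", "compact")),
    m("GluN2D", "NTD-W56", "glutamate_only",
      mean_fret = c(0.18, 0.68), occupancies = c(0.20, 0.80),
      label = c("splayed", "compact"))
  )
}

#' List the packaged condition models
#'
#' @return A tibble with one row per packaged (subtype, probe_site,
#'   ligand_condition) triple and a summary of its states.
#' @export
condition_model_keys <- function() {
  lib <- condition_library()
  tibble::tibble(
    subtype = vapply(lib, `[[`, "", "subtype"),
    probe_site = vapply(lib, `[[`, "", "probe_site"),
    ligand_condition = vapply(lib, `[[`, "", "ligand_condition"),
    n_states = vapply(lib, function(m) nrow(m$states), 0L),
    peaks = vapply(lib, function(m)
      paste(sprintf("%.2f", m$states$mean_fret), collapse = "/"), ""))
}

#' Retrieve a packaged condition model
#'
#' Looks up the packaged state model for one receptor subtype, GluN1 probe
#' site, and ligand condition. Peak FRET values match the published
#' distributions; occupancies encode the published major/minor descriptions
#' (the texts give no percentages, so these are declared approximations).
#'
#' @inheritParams state_model
#' @return A [state_model()] object.
#' @examples
#' condition_model("GluN2D", "NTD-W56", "apo_like")
#' @export
condition_model <- function(subtype, probe_site, ligand_condition) {
  lib <- condition_library()
  for (mod in lib) {
    if (identical(mod$subtype, subtype) &&
        identical(mod$probe_site, probe_site) &&
        identical(mod$ligand_condition, ligand_condition))
      return(mod)
  }
  keys <- condition_model_keys()
  abort_smfret(sprintf(
    "no packaged model for (%s, %s, %s); valid keys:\n%s",
    subtype, probe_site, ligand_condition,
    paste(sprintf("  %s / %s / %s", keys$subtype, keys$probe_site,
                  keys$ligand_condition), collapse = "\n")))
}
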