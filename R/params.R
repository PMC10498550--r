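#' Prolate-spheroid chamber volume
#'
#' Single-view volume estimate under the prolate-spheroid assumption:
#' `V = (pi/6) * length * diameter^2`, with the long axis as the spheroid's
#' major axis and the mid-length diameter as both minor axes.
#'
#' @param length chamber length in um (>= 0).
#' @param diameter chamber diameter in um (>= 0).
#' @return volume in um^3 (vectorised).
#' @export
#' @examples
#' prolate_volume(100, 50)
prolate_volume <- function(length, diameter) {
  if (any(!is.finite(length)) || any(!is.finite(diameter)) ||
      any(length < 0) || any(diameter < 0)) {
    abort_invalid_parameter("`length` and `diameter` must be finite and non-negative.")
  }
  (pi / 6) * length * diameter^2
}

#' Per-cycle cardiac measurement from an ED/ES geometry pair
#'
#' Evaluates the per-cycle chamber equations on the end-diastole and
#' end-systole frame geometries of one contraction cycle:
#' EDV and ESV by [prolate_volume()]; stroke volume `SV = EDV - ESV`;
#' ejection fraction `EF = SV/EDV * 100` (%); fractional shortening
#' `FS = (Dd - Ds)/Dd`; fractional area change `FAC = (Ad - As)/Ad * 100`
#' (%).
#'
#' @param ed_geom,es_geom one-row geometry tibbles ([frame_geometry()]
#'   rows) for the end-diastole and end-systole frames of one cycle.
#' @return a one-row tibble with `ed_frame`, `es_frame`, per-phase `L`,
#'   `D`, `area`, and `EDV_um3`, `ESV_um3`, `SV_um3`, `EF_pct`, `FS`,
#'   `FAC_pct`.
#' @export
cycle_measurement <- function(ed_geom, es_geom) {
  for (g in list(ed_geom, es_geom)) {
    if (!is.data.frame(g) || nrow(g) != 1L ||
        !all(c("area_um2", "length_um", "diameter_um") %in% names(g))) {
      abort_invalid_input("`ed_geom` and `es_geom` must be one-row geometry tables.")
    }
  }
  EDV <- prolate_volume(ed_geom$length_um, ed_geom$diameter_um)
  ESV <- prolate_volume(es_geom$length_um, es_geom$diameter_um)
  SV <- EDV - ESV
  if (SV < 0) {
    abort("ESV exceeds EDV: the ED/ES pair is mis-detected (end-systole larger than end-diastole).",
          class = c("zfcardio_invalid_pair", "zfcardio_invalid_input"))
  }
  if (EDV == 0) abort_degenerate("EDV is zero: ejection fraction is undefined.")
  if (ed_geom$diameter_um == 0) abort_degenerate("Diastolic diameter is zero: fractional shortening is undefined.")
  if (ed_geom$area_um2 == 0) abort_degenerate("Diastolic area is zero: fractional area change is undefined.")
  tibble(
    ed_frame = ed_geom$frame %||% NA_integer_,
    es_frame = es_geom$frame %||% NA_integer_,
    Ld_um = ed_geom$length_um, Dd_um = ed_geom$diameter_um,
    Ad_um2 = ed_geom$area_um2,
    Ls_um = es_geom$length_um, Ds_um = es_geom$diameter_um,
    As_um2 = es_geom$area_um2,
    EDV_um3 = EDV, ESV_um3 = ESV, SV_um3 = SV,
    EF_pct = SV / EDV * 100,
    FS = (ed_geom$diameter_um - es_geom$diameter_um) / ed_geom$diameter_um,
    FAC_pct = (ed_geom$area_um2 - es_geom$area_um2) / ed_geom$area_um2 * 100
  )
}

#' Per-fish cardiac parameter summary
#'
#' Arithmetic mean of every per-cycle quantity over all captured cycles of
#' one fish (each parameter is evaluated per cycle first, then averaged),
#' plus heart rate and cardiac output `CO = mean(SV) * HR`. Fish with
#' fewer than `min_cycles` cycles are rejected rather than averaged, the
#' same exclusion applied when each data point must represent at least
#' three contraction cycles. Volumes are also reported in nL
#' (1 nL = 1e6 um^3).
#'
#' @param cycles tibble of per-cycle measurements ([cycle_measurement()]
#'   rows).
#' @param heart_rate heart rate in Hz ([heart_rate()]).
#' @param min_cycles minimum number of cycles required (default 3).
#' @param id fish identifier.
#' @return a one-row tibble: `id`, `n_cycles`, mean `EDV`/`ESV`/`SV` in
#'   um^3 and nL, `EF_pct`, `FS`, `FAC_pct`, `HR_hz`, `CO_um3_per_s`,
#'   `CO_nl_per_s`, `CO_nl_per_min`.
#' @export
per_fish_summary <- function(cycles, heart_rate, min_cycles = 3L, id = "fish") {
  if (!is.data.frame(cycles)) abort_invalid_input("`cycles` must be a data frame of cycle measurements.")
  if (nrow(cycles) < min_cycles) {
    abort(sprintf("Only %d cycle(s) measured; at least %d are required per fish.",
                  nrow(cycles), min_cycles),
          class = "zfcardio_insufficient_cycles")
  }
  check_positive_scalar(heart_rate, "heart_rate")
  m <- function(col) mean(cycles[[col]])
  sv <- m("SV_um3")
  tibble(
    id = as.character(id),
    n_cycles = nrow(cycles),
    EDV_um3 = m("EDV_um3"), ESV_um3 = m("ESV_um3"), SV_um3 = sv,
    EDV_nl = m("EDV_um3") / UM3_PER_NL, ESV_nl = m("ESV_um3") / UM3_PER_NL,
    SV_nl = sv / UM3_PER_NL,
    EF_pct = m("EF_pct"), FS = m("FS"), FAC_pct = m("FAC_pct"),
    HR_hz = heart_rate, HR_bpm = heart_rate * 60,
    CO_um3_per_s = sv * heart_rate,
    CO_nl_per_s = sv * heart_rate / UM3_PER_NL,
    CO_nl_per_min = sv * heart_rate * 60 / UM3_PER_NL
  )
}
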