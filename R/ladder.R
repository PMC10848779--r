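## Sequential-electron-transfer energetics: typed excited-state ladders
## with unit conversion, gap arithmetic, channel classification and
## consistency validation. Packaged datasets live under inst/extdata.

#' Convert between photon energy (eV) and wavelength (nm)
#'
#' lambda = 1239.84198 / E and vice versa; the conversion is an
#' involution (round trip identity).
#'
#' @param value Positive energy (eV) or wavelength (nm).
#' @param direction `"eV_to_nm"` or `"nm_to_eV"`.
#' @return Converted value.
#' @export
energy_wavelength_convert <- function(value,
                                      direction = c("eV_to_nm", "nm_to_eV")) {
  direction <- match.arg(direction)
  if (any(!is.finite(value)) || any(value <= 0))
    stop("value must be positive")
  photo_constants$eV_nm / value
}

#' Construct a sequential-electron-transfer energy ladder
#'
#' A ladder bundles vertical excitation states (Franck-Condon region) and
#' excited-state stationary points (S1 minima and S1/S0 minimum-energy
#' crossing points) of one stacked conformer. Point energies are relative
#' to the ground-state minimum; points whose absolute energy is not
#' reported carry `NA` and are connected through signed `gaps` records
#' instead.
#'
#' @param system_label e.g. `"TTAG AG-anti"`.
#' @param states Data frame: `label`, `character` (LE/CT),
#'   `transition_note`, `energy_eV`, `oscillator_strength`,
#'   `wavelength_nm`.
#' @param points Data frame: `name`, `kind` (minimum/MECP), `energy_eV`
#'   (may be NA), `provenance`.
#' @param gaps Data frame: `from`, `to`, `delta_eV` (signed, to - from),
#'   `provenance`. May be empty.
#' @param bright_state_energy_eV Vertical energy of the lowest optically
#'   bright state (NA if not reported).
#' @return An object of class `"set_ladder"`.
#' @export
set_ladder <- function(system_label, states, points, gaps = NULL,
                       bright_state_energy_eV = NA_real_) {
  states <- as.data.frame(states)
  points <- as.data.frame(points)
  if (is.null(gaps))
    gaps <- data.frame(from = character(0), to = character(0),
                       delta_eV = numeric(0), provenance = character(0))
  gaps <- as.data.frame(gaps)
  if (nrow(points) == 0) stop("validation error: empty points list")
  if (sum(points$name == "FC") != 1)
    stop("a ladder must contain exactly one FC entry")
  if (!all(points$kind %in% c("minimum", "MECP")))
    stop("point kind must be 'minimum' or 'MECP'")
  bad <- setdiff(c(gaps$from, gaps$to), points$name)
  if (length(bad))
    stop("gap references unknown point(s): ", paste(bad, collapse = ", "))
  e <- points$energy_eV
  if (any(!is.na(e) & e <= 0))
    stop("excited-state point energies must be positive")
  structure(list(system_label = system_label, states = states,
                 points = points, gaps = gaps,
                 bright_state_energy_eV = bright_state_energy_eV),
            class = "set_ladder")
}

#' @export
print.set_ladder <- function(x, ...) {
  cat(sprintf("<SET ladder: %s; %d states, %d points, %d gap records>\n",
              x$system_label, nrow(x$states), nrow(x$points), nrow(x$gaps)))
  invisible(x)
}

#' Read a ladder from its JSON representation
#' @param path JSON file.
#' @return A `set_ladder`.
#' @export
read_set_ladder <- function(path) {
  j <- jsonlite::read_json(path, simplifyVector = TRUE)
  set_ladder(j$system_label, j$states, j$points, j$gaps,
             if (is.null(j$bright_state_energy_eV)) NA_real_
             else j$bright_state_energy_eV)
}

#' Load a packaged ladder dataset
#'
#' Ships the ADC(2)-characterized excited-state ladders of the damaged
#' tetranucleotides: `"ttag_ag_anti"` (absolute energies anchored at the
#' reported 4.27 eV G* minimum), `"gatt_ga_syn"` and `"gatt_ga_anti"`
#' (gap records only where absolute anchors were not reported).
#'
#' @param system Dataset name.
#' @return A `set_ladder`.
#' @export
load_set_ladder <- function(system = c("ttag_ag_anti", "gatt_ga_syn",
                                       "gatt_ga_anti")) {
  system <- match.arg(system)
  read_set_ladder(system.file("extdata", paste0(system, ".json"),
                              package = "photorepair", mustWork = TRUE))
}

point_row <- function(ladder, name) {
  i <- which(ladder$points$name == name)
  if (!length(i))
    stop(sprintf("unknown point '%s'; available: %s", name,
                 paste(ladder$points$name, collapse = ", ")))
  ladder$points[i[1], ]
}

#' Signed energy gap between two stationary points
#'
#' Returns E(to) - E(from) in eV. Gaps are resolved preferentially
#' through the ladder's signed gap records (path-additive over the gap
#' graph, so transcribed values are reproduced exactly); where no
#' gap-record path exists, absolute point energies are differenced.
#'
#' @param ladder A `set_ladder`.
#' @param from,to Point names.
#' @return Signed gap (eV); antisymmetric in its arguments.
#' @export
ladder_gap <- function(ladder, from, to) {
  point_row(ladder, from); point_row(ladder, to)
  if (from == to) return(0)
  ## breadth-first search over the signed gap records
  dist <- stats::setNames(rep(NA_real_, nrow(ladder$points)),
                          ladder$points$name)
  dist[from] <- 0
  queue <- from
  while (length(queue)) {
    cur <- queue[1]; queue <- queue[-1]
    if (cur == to) return(unname(dist[to]))
    g <- ladder$gaps
    fwd <- which(g$from == cur); bwd <- which(g$to == cur)
    for (i in fwd) if (is.na(dist[g$to[i]])) {
      dist[g$to[i]] <- dist[cur] + g$delta_eV[i]; queue <- c(queue, g$to[i])
    }
    for (i in bwd) if (is.na(dist[g$from[i]])) {
      dist[g$from[i]] <- dist[cur] - g$delta_eV[i]; queue <- c(queue, g$from[i])
    }
  }
  eF <- point_row(ladder, from)$energy_eV
  eT <- point_row(ladder, to)$energy_eV
  if (is.na(eF) || is.na(eT))
    stop(sprintf("gap %s -> %s cannot be resolved: no gap-record path and missing absolute energies",
                 from, to))
  eT - eF
}

#' Classify a decay channel as accessible or hindered
#'
#' A channel from an S1 minimum to an S1/S0 MECP is accessible when the
#' uphill gap does not exceed the barrier threshold (default 0.1 eV).
#'
#' @param ladder A `set_ladder`.
#' @param from_min Name of a point of kind `minimum`.
#' @param to_mecp Name of a point of kind `MECP`.
#' @param threshold_eV Accessibility threshold.
#' @return `"accessible"` or `"hindered"`.
#' @export
classify_channel <- function(ladder, from_min, to_mecp, threshold_eV = 0.1) {
  pf <- point_row(ladder, from_min)
  pt <- point_row(ladder, to_mecp)
  if (pf$kind != "minimum")
    stop(sprintf("'%s' is not a minimum (kind: %s)", from_min, pf$kind))
  if (pt$kind != "MECP")
    stop(sprintf("'%s' is not an MECP (kind: %s)", to_mecp, pt$kind))
  if (ladder_gap(ladder, from_min, to_mecp) <= threshold_eV)
    "accessible" else "hindered"
}

absolute_energy <- function(ladder, name) {
  e <- point_row(ladder, name)$energy_eV
  if (!is.na(e)) return(e)
  anchored <- ladder$points$name[!is.na(ladder$points$energy_eV)]
  for (a in anchored) {
    g <- tryCatch(ladder_gap(ladder, a, name), error = function(e) NA)
    if (!is.na(g)) return(point_row(ladder, a)$energy_eV + g)
  }
  NA_real_
}

#' Run consistency checks on a ladder
#'
#' Checks (reported, never thrown): exactly one FC entry; state
#' wavelength/energy consistency within 0.5 nm; positive point energies;
#' the MECP above the A radical-anion CT minimum lies above the bright
#' vertical state; the SET cascade minima are energetically downhill
#' (G* >= A-G+ >= TT-AG+ where those points exist).
#'
#' @param ladder A `set_ladder`.
#' @return Data frame with `check`, `passed`, `detail`.
#' @export
validate_ladder <- function(ladder) {
  out <- list()
  add <- function(check, passed, detail = "")
    out[[length(out) + 1]] <<- data.frame(check = check, passed = passed,
                                          detail = detail)
  add("one FC entry", sum(ladder$points$name == "FC") == 1,
      sprintf("%d found", sum(ladder$points$name == "FC")))
  if (nrow(ladder$states)) {
    dev <- abs(ladder$states$wavelength_nm -
                 photo_constants$eV_nm / ladder$states$energy_eV)
    add("state wavelength/energy consistency (<= 0.5 nm)", all(dev <= 0.5),
        sprintf("max deviation %.3f nm", max(dev)))
  }
  e <- ladder$points$energy_eV
  add("positive point energies", all(is.na(e) | e > 0), "")
  if ("MECP_AG" %in% ladder$points$name &&
      !is.na(ladder$bright_state_energy_eV)) {
    ea <- absolute_energy(ladder, "MECP_AG")
    if (is.na(ea)) {
      add("MECP above bright state", NA, "absolute MECP energy not resolvable")
    } else {
      add("MECP above bright state", ea > ladder$bright_state_energy_eV,
          sprintf("MECP_AG %.2f eV vs bright %.2f eV", ea,
                  ladder$bright_state_energy_eV))
    }
  }
  casc <- c("G*", "A-G+", "TT-AG+")
  if (all(casc %in% ladder$points$name)) {
    ec <- vapply(casc, function(p) absolute_energy(ladder, p), numeric(1))
    add("downhill SET cascade", !any(is.na(ec)) && all(diff(ec) <= 0),
        paste(sprintf("%.2f", ec), collapse = " >= "))
  }
  do.call(rbind, out)
}
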