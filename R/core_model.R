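#' Charge attractivity of an entering ion
#'
#' First gate of the charge-permeability model: an entering ion of charge
#' \eqn{q_i} is drawn to a selectivity filter of ring charge \eqn{r_q}
#' whenever the two do not exactly neutralise each other,
#' \deqn{A(r_q, q_i) = 1 \iff |r_q + q_i| > 0.}
#' The single failure mode is exact cancellation (\eqn{q_i = -r_q}): a +1 ion
#' loses attractivity only at \eqn{r_q = -1}, a +2 ion only at \eqn{r_q = -2}.
#'
#' @param r_q Integer ring charge of the selectivity filter, `r_q <= 0`.
#' @param ion_in Entering ion: an [ion()] object or a registered ion name.
#' @return `0L` or `1L`.
#' @seealso [inward_drive()], [permeability()]
#' @export
#' @examples
#' attractivity(-2, "Ca2+")  # exact neutralisation: 0
#' attractivity(-1, "Na+")   # 0
#' attractivity(-4, "Na+")   # 1
attractivity <- function(r_q, ion_in) {
  r <- .check_ring(r_q)
  qi <- as_ion(ion_in)$valence
  as.integer(abs(r + qi) > 0L)
}

#' Inward drive of an entering ion against the pore resident
#'
#' Second gate: once attracted, the entering ion must displace whatever
#' occupies the pore. The resident ion of charge \eqn{q_r} neutralises part
#' of the ring, leaving residual ring charge \eqn{|r_q + q_r|}; the entering
#' ion drives it inward when
#' \deqn{B(r_q, q_i, q_r) = 1 \iff q_i + |r_q + q_r| > q_r.}
#' An empty pore contributes resident charge 0.
#'
#' @inheritParams attractivity
#' @param pore Pore occupancy: `"EMPTY"` (default), an ion name, or an
#'   [ion()] object (see [as_pore()]).
#' @return `0L` or `1L`.
#' @export
#' @examples
#' inward_drive(-4, "Na+", "Ca2+")  # Na+ can displace Ca2+ at r_q = -4: 1
#' inward_drive(-3, "Na+", "Ca2+")  # ...but not at r_q = -3: 0
inward_drive <- function(r_q, ion_in, pore = "EMPTY") {
  r <- .check_ring(r_q)
  qi <- as_ion(ion_in)$valence
  qr <- as_pore(pore)$q_r
  as.integer(qi + abs(r + qr) > qr)
}

#' Binary permeability verdict with full working
#'
#' Evaluates the charge-permeability equation
#' \deqn{\mathrm{permeable} = A(r_q, q_i) \times B(r_q, q_i, q_r)}
#' and returns every intermediate quantity, so the verdict can be audited
#' cell-by-cell rather than taken as a bare bit.
#'
#' @inheritParams inward_drive
#' @return A `permeability_verdict` object: a list with integer fields
#'   `r_q`, `q_i`, `q_r`, `ion_in`, `occupant`, `attractivity`,
#'   `residual_ring` (\eqn{|r_q + q_r|}), `drive_lhs`
#'   (\eqn{q_i + |r_q + q_r|}), `inward_drive` and `permeable`.
#' @export
#' @examples
#' permeability(-3, "Na+", "Ca2+")   # attracted but cannot displace: 0
#' permeability(-2, "Na+", "Na+")    # self-displacement at -2: 1
permeability <- function(r_q, ion_in, pore = "EMPTY") {
  r <- .check_ring(r_q)
  ii <- as_ion(ion_in)
  po <- as_pore(pore)
  a <- as.integer(abs(r + ii$valence) > 0L)
  residual <- abs(r + po$q_r)
  lhs <- ii$valence + residual
  b <- as.integer(lhs > po$q_r)
  structure(
    list(
      r_q = r, q_i = ii$valence, q_r = po$q_r,
      ion_in = ii$name, occupant = po$occupant,
      attractivity = a, residual_ring = residual,
      drive_lhs = lhs, inward_drive = b,
      permeable = a * b
    ),
    class = "permeability_verdict"
  )
}

#' @export
print.permeability_verdict <- function(x, ...) {
  cat(sprintf(
    "<permeability verdict> %s entering pore [%s], r_q = %d\n",
    x$ion_in, x$occupant, x$r_q
  ))
  print(working_table(x), row.names = FALSE)
  invisible(x)
}

#' Ordered working table for a permeability verdict
#'
#' Renders the verdict as the row sequence used under the displacement-test
#' schematics: the attractivity test, the residual (partially neutralised)
#' ring, the inward-drive test, and the final product. Deterministic and
#' machine-readable, suitable for TSV or JSON emission.
#'
#' @param r_q A ring charge, or a ready-made [permeability()] verdict (in
#'   which case `ion_in` and `pore` are ignored).
#' @inheritParams inward_drive
#' @return A data.frame with columns `step`, `quantity`, `expression`,
#'   `value`.
#' @export
#' @examples
#' working_table(-3, "Na+", "Ca2+")
working_table <- function(r_q, ion_in = NULL, pore = "EMPTY") {
  v <- if (inherits(r_q, "permeability_verdict")) r_q else {
    permeability(r_q, ion_in, pore)
  }
  data.frame(
    step = 1:5,
    quantity = c("attractivity_A", "residual_ring", "drive_lhs",
                 "inward_drive_B", "permeable"),
    expression = c(
      sprintf("|r_q + q_i| = |%d + %d| > 0", v$r_q, v$q_i),
      sprintf("|r_q + q_r| = |%d + %d|", v$r_q, v$q_r),
      sprintf("q_i + |r_q + q_r| = %d + %d", v$q_i, v$residual_ring),
      sprintf("q_i + |r_q + q_r| > q_r : %d > %d", v$drive_lhs, v$q_r),
      "A * B"
    ),
    value = c(v$attractivity, v$residual_ring, v$drive_lhs,
              v$inward_drive, v$permeable),
    stringsAsFactors = FALSE
  )
}

#' JSON serialization of a permeability verdict
#'
#' Stable key names: `r_q`, `q_i`, `q_r`, `A`, `B`, `residual`, `permeable`
#' (plus the ion labels).
#'
#' @param verdict A [permeability()] verdict.
#' @param pretty Pretty-print the JSON?
#' @return A JSON string (class `json`).
#' @export
#' @examples
#' verdict_json(permeability(-4, "Ca2+", "Na+"))
verdict_json <- function(verdict, pretty = FALSE) {
  stopifnot(inherits(verdict, "permeability_verdict"))
  jsonlite::toJSON(
    list(
      r_q = verdict$r_q, q_i = verdict$q_i, q_r = verdict$q_r,
      ion_in = verdict$ion_in, occupant = verdict$occupant,
      A = verdict$attractivity, residual = verdict$residual_ring,
      B = verdict$inward_drive, permeable = verdict$permeable
    ),
    auto_unbox = TRUE, pretty = pretty
  )
}
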