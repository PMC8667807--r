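#' Built-in ion registry
#'
#' The ions the model is routinely queried with: Na+ and K+ (monovalent
#' cations, charge +1), Ca2+ and Mg2+ (divalent cations, +2) and Cl-
#' (monovalent anion, -1). The model distinguishes ions only by their signed
#' integer valence, so K+ behaves exactly like Na+ and Mg2+ exactly like
#' Ca2+; both are included so queries can be phrased in either species.
#'
#' @return A data.frame with columns `name` and `valence`.
#' @export
#' @examples
#' ion_registry()
ion_registry <- function() {
  data.frame(
    name    = c("Na+", "K+", "Ca2+", "Mg2+", "Cl-"),
    valence = c(1L, 1L, 2L, 2L, -1L),
    stringsAsFactors = FALSE
  )
}

#' Create or look up an ion species
#'
#' @param name Ion label. Built-in names (`"Na+"`, `"K+"`, `"Ca2+"`, `"Mg2+"`,
#'   `"Cl-"`) may be given with or without the charge suffix and in any case
#'   (`"na"`, `"Ca"`, `"cl"` all resolve). Unknown names require an explicit
#'   `valence`.
#' @param valence Signed integer charge; required for custom ions, ignored
#'   (but checked for consistency) for built-ins. Must be a nonzero integer.
#' @return An object of class `ion_species` with fields `name` and `valence`.
#' @export
#' @examples
#' ion("Na+")
#' ion("ca")          # resolves to Ca2+
#' ion("Ba2+", 2)     # custom divalent cation
ion <- function(name, valence = NULL) {
  stopifnot(is.character(name), length(name) == 1L, nzchar(name))
  reg <- ion_registry()
  canon <- .canon_ion_name(name)
  hit <- match(canon, .canon_ion_name(reg$name))
  if (!is.na(hit)) {
    v <- reg$valence[hit]
    if (!is.null(valence) && as.integer(valence) != v) {
      stop("ion '", reg$name[hit], "' has valence ", v,
           ", not ", valence, call. = FALSE)
    }
    return(structure(list(name = reg$name[hit], valence = v),
                     class = "ion_species"))
  }
  if (is.null(valence)) {
    stop("unknown ion '", name, "'; supply a valence to define a custom ion",
         call. = FALSE)
  }
  v <- .check_integerish(valence, "valence")
  if (v == 0L) stop("ion valence must be a nonzero integer", call. = FALSE)
  structure(list(name = name, valence = v), class = "ion_species")
}

# charge-suffix-insensitive, case-insensitive key for built-in lookup
.canon_ion_name <- function(x) tolower(gsub("[0-9+-]+$", "", x))

#' @export
print.ion_species <- function(x, ...) {
  cat(sprintf("<ion> %s (valence %+d)\n", x$name, x$valence))
  invisible(x)
}

#' @rdname ion
#' @param x An `ion_species`, an ion name, or (for `as_pore`) `"EMPTY"` / `NA`
#'   / `NULL` for an unoccupied pore.
#' @export
as_ion <- function(x) {
  if (inherits(x, "ion_species")) return(x)
  if (is.character(x) && length(x) == 1L) return(ion(x))
  stop("cannot interpret ", deparse(substitute(x)), " as an ion species",
       call. = FALSE)
}

#' Resolve a pore-occupancy argument
#'
#' The pore is either empty (resident charge contributes 0) or occupied by a
#' single resident ion. `"EMPTY"`, `NA` and `NULL` all denote the empty pore.
#'
#' @inheritParams as_ion
#' @return A list with fields `occupant` (`"EMPTY"` or ion name) and `q_r`
#'   (resident charge; 0 when empty).
#' @export
#' @examples
#' as_pore("EMPTY")
#' as_pore("Ca2+")
as_pore <- function(x) {
  if (is.null(x) || (length(x) == 1L && is.na(x)) ||
      (is.character(x) && length(x) == 1L && toupper(x) == "EMPTY")) {
    return(list(occupant = "EMPTY", q_r = 0L))
  }
  i <- as_ion(x)
  list(occupant = i$name, q_r = i$valence)
}

.check_integerish <- function(x, what) {
  if (length(x) != 1L || is.na(x) || !is.numeric(x) || x != round(x)) {
    stop(what, " must be a single integer, got ",
         deparse(x), call. = FALSE)
  }
  as.integer(x)
}

# shared validation: the model is defined only for non-positive integer rings
.check_ring <- function(r_q) {
  r <- .check_integerish(r_q, "ring charge r_q")
  if (r > 0L) {
    stop("ring charge r_q must satisfy r_q <= 0 (the selectivity-filter ",
         "ring is never net positive); got ", r, call. = FALSE)
  }
  r
}
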