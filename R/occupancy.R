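#' Build the pore occupancy-state transition structure
#'
#' Channel-level selectivity emerges from how single displacement events
#' chain together. States are `EMPTY` plus one occupied state per ambient
#' ion; a directed edge `s -> i` exists exactly when the charge-permeability
#' verdict allows ion `i` to enter a pore in state `s` (the displaced
#' resident exits inward and the enterer takes its place). `EMPTY` is never
#' re-entered: permeation is displacement with immediate re-occupation, so
#' `EMPTY` is at most a start state. Long-run behaviour is read off the
#' strongly connected components: the terminal (absorbing/recurrent) classes
#' reachable from `EMPTY` are where the channel ends up.
#'
#' @param r_q Integer ring charge, `r_q <= 0`.
#' @param ambient Non-empty set of ambient ions (names or [ion()] objects).
#' @return An `occupancy_model`: list with `r_q`, `ambient` (named integer
#'   valences), `states`, `edges` (data.frame `from`, `to`), `scc`
#'   (membership named by state), `reachable` (states reachable from
#'   `EMPTY`, inclusive), `terminal_classes` (list of state sets: terminal
#'   SCCs of the reachable subgraph).
#' @export
#' @examples
#' m <- build_occupancy_model(-3, c("Na+", "Ca2+"))
#' m$edges                    # Ca2+-occupied is absorbing at r_q = -3
#' m$terminal_classes
build_occupancy_model <- function(r_q, ambient) {
  r <- .check_ring(r_q)
  if (length(ambient) == 0L) stop("ambient ion set is empty", call. = FALSE)
  ions <- lapply(ambient, as_ion)
  nm <- vapply(ions, `[[`, "", "name")
  if (anyDuplicated(nm)) stop("duplicate ambient ions", call. = FALSE)
  val <- setNames(vapply(ions, `[[`, 0L, "valence"), nm)
  states <- c("EMPTY", nm)

  from <- character(0); to <- character(0)
  for (s in states) {
    for (i in nm) {
      if (permeability(r, ion(i, val[[i]]), if (s == "EMPTY") "EMPTY" else
                       ion(s, val[[s]]))$permeable == 1L) {
        from <- c(from, s); to <- c(to, i)
      }
    }
  }
  edges <- data.frame(from = from, to = to, stringsAsFactors = FALSE)

  g <- igraph::graph_from_data_frame(
    edges, directed = TRUE,
    vertices = data.frame(name = states, stringsAsFactors = FALSE)
  )
  scc <- igraph::components(g, mode = "strong")$membership
  dist <- igraph::distances(g, v = "EMPTY", mode = "out")
  reachable <- states[is.finite(dist[1, states])]

  # terminal SCCs of the subgraph induced by the reachable states
  sub <- igraph::induced_subgraph(g, reachable)
  sub_scc <- igraph::components(sub, mode = "strong")$membership
  sub_edges <- igraph::as_data_frame(sub, what = "edges")
  terminal <- lapply(sort(unique(sub_scc)), function(k) {
    members <- names(sub_scc)[sub_scc == k]
    leaving <- sub_edges$from %in% members & !(sub_edges$to %in% members)
    if (any(leaving)) NULL else members
  })
  terminal <- Filter(Negate(is.null), terminal)

  structure(
    list(r_q = r, ambient = val, states = states, edges = edges,
         scc = scc, reachable = reachable, terminal_classes = terminal),
    class = "occupancy_model"
  )
}

#' @export
print.occupancy_model <- function(x, ...) {
  cat(sprintf("<occupancy model> r_q = %d, ambient: %s\n",
              x$r_q, paste(names(x$ambient), collapse = ", ")))
  if (nrow(x$edges)) {
    cat("  transitions:",
        paste(sprintf("%s->%s", x$edges$from, x$edges$to), collapse = ", "),
        "\n")
  } else cat("  transitions: none\n")
  cat("  terminal classes reachable from EMPTY:",
      paste(vapply(x$terminal_classes, paste, "", collapse = "+"),
            collapse = "; "), "\n")
  invisible(x)
}

#' Per-ion selectivity classes of an occupancy model
#'
#' Three nested readings of "permeable" for each ambient ion:
#' * `unconditional` — enters from every state (`EMPTY` and every occupied
#'   state), so permeation never stalls;
#' * `steady_state` — enters from every state of every terminal
#'   (absorbing/recurrent) class reachable from `EMPTY`: the long-run
#'   verdict once transients have washed out. With several terminal classes
#'   the conservative intersection is reported (permeable in all of them);
#'   per-class detail is in the `per_class` attribute.
#' * `conditional` — enters from at least one state but not unconditionally.
#'
#' `unconditional = 1` implies `steady_state = 1`.
#'
#' @param model An [build_occupancy_model()] result.
#' @return A data.frame, one row per ambient ion: `ion`, `unconditional`,
#'   `steady_state`, `conditional`.
#' @export
#' @examples
#' classify_selectivity(build_occupancy_model(-3, c("Na+", "Ca2+")))
classify_selectivity <- function(model) {
  stopifnot(inherits(model, "occupancy_model"))
  nm <- names(model$ambient)
  has_edge <- function(s, i) {
    any(model$edges$from == s & model$edges$to == i)
  }
  per_class <- lapply(model$terminal_classes, function(cls) {
    setNames(vapply(nm, function(i) {
      as.integer(all(vapply(cls, has_edge, TRUE, i = i)))
    }, 0L), nm)
  })
  out <- data.frame(
    ion = nm,
    unconditional = vapply(nm, function(i) {
      as.integer(all(vapply(model$states, has_edge, TRUE, i = i)))
    }, 0L),
    steady_state = vapply(nm, function(i) {
      as.integer(all(vapply(per_class, `[[`, 0L, i)))
    }, 0L),
    stringsAsFactors = FALSE, row.names = NULL
  )
  some <- vapply(nm, function(i) {
    any(vapply(model$states, has_edge, TRUE, i = i))
  }, TRUE)
  out$conditional <- as.integer(some & out$unconditional == 0L)
  attr(out, "per_class") <- per_class
  out
}

#' Selectivity profile over a ring-charge range
#'
#' Classifies every ambient ion at every integer ring charge in the range,
#' giving the binary permeability-versus-ring-charge relationship under both
#' the steady-state and the unconditional reading.
#'
#' @param r_q_range Inclusive integer interval, e.g. `c(-4, 0)`; must lie
#'   within `[-8, 0]`.
#' @param ambient Ambient ion set; default Na+ and Ca2+.
#' @return A data.frame with one row per (r_q, ion): columns `r_q`, `ion`,
#'   `unconditional`, `steady_state`, `conditional`.
#' @export
#' @examples
#' selectivity_profile(c(-4, 0))
selectivity_profile <- function(r_q_range, ambient = c("Na+", "Ca2+")) {
  rng <- .check_range(r_q_range)
  rows <- lapply(seq(rng[1], rng[2]), function(r) {
    cls <- classify_selectivity(build_occupancy_model(r, ambient))
    cbind(r_q = r, cls)
  })
  do.call(rbind, rows)
}

.check_range <- function(r_q_range, floor = -8L) {
  stopifnot(length(r_q_range) == 2L)
  lo <- .check_integerish(min(r_q_range), "range bound")
  hi <- .check_integerish(max(r_q_range), "range bound")
  if (lo < floor || hi > 0L) {
    stop("ring-charge range must lie within [", floor, ", 0]", call. = FALSE)
  }
  c(lo, hi)
}

#' Scan chloride permeability against ring charge
#'
#' For each possible resident species (empty pore, each ambient cation, and
#' Cl- itself) reports the ring-charge interval within the scanned range
#' where Cl- entry is blocked, and the least-negative ring charge at which
#' Cl- is unconditionally permeable (enters from every occupancy state). If
#' the scanned range is too narrow to witness that threshold, the result
#' says so explicitly rather than guessing.
#'
#' @param r_q_range Inclusive integer interval within `[-8, 0]`; the default
#'   `c(-6, 0)` covers every documented claim.
#' @param ambient Cation set to scan alongside Cl-; Cl- is added to the
#'   state space automatically if absent.
#' @return An `anion_scan` object: list with `r_q_range`, `occlusion` (one
#'   row per resident: `resident`, `blocked_from`, `blocked_to`, `n_blocked`;
#'   bounds are `NA` when never blocked in range) and
#'   `unconditional_threshold` (integer, or `NA` with `threshold_status =
#'   "undetermined within range"`).
#' @export
#' @examples
#' anion_scan(c(-6, 0))
anion_scan <- function(r_q_range = c(-6, 0), ambient = c("Na+", "Ca2+")) {
  rng <- .check_range(r_q_range)
  ions <- lapply(ambient, as_ion)
  nm <- vapply(ions, `[[`, "", "name")
  if (!"Cl-" %in% nm) {
    ions <- c(ions, list(ion("Cl-")))
    nm <- c(nm, "Cl-")
  }
  residents <- c("EMPTY", nm)
  rqs <- seq(rng[2], rng[1])  # scan downward from the least negative

  blocked <- vapply(residents, function(res) {
    vapply(rqs, function(r) {
      permeability(r, "Cl-", if (res == "EMPTY") "EMPTY" else res)$permeable == 0L
    }, TRUE)
  }, logical(length(rqs)))
  blocked <- matrix(blocked, nrow = length(rqs),
                    dimnames = list(NULL, residents))

  occl <- data.frame(
    resident = residents,
    blocked_from = vapply(residents, function(res) {
      b <- rqs[blocked[, res]]
      if (length(b)) min(b) else NA_integer_
    }, 0L),
    blocked_to = vapply(residents, function(res) {
      b <- rqs[blocked[, res]]
      if (length(b)) max(b) else NA_integer_
    }, 0L),
    n_blocked = as.integer(colSums(blocked)),
    stringsAsFactors = FALSE, row.names = NULL
  )

  uncond <- rqs[rowSums(blocked) == 0L]
  if (length(uncond)) {
    thr <- uncond[1]  # first hit scanning downward = least negative
    status <- "determined"
  } else {
    thr <- NA_integer_
    status <- "undetermined within range"
  }
  structure(
    list(r_q_range = rng, occlusion = occl,
         unconditional_threshold = thr, threshold_status = status),
    class = "anion_scan"
  )
}

#' @export
print.anion_scan <- function(x, ...) {
  cat(sprintf("<anion scan> Cl- entry over r_q in [%d, %d]\n",
              x$r_q_range[1], x$r_q_range[2]))
  print(x$occlusion, row.names = FALSE)
  if (is.na(x$unconditional_threshold)) {
    cat("  unconditional Cl- permeability:", x$threshold_status, "\n")
  } else {
    cat("  Cl- first unconditionally permeable at r_q =",
        x$unconditional_threshold, "\n")
  }
  invisible(x)
}

#' Export an occupancy model's transitions
#'
#' @param model An [build_occupancy_model()] result.
#' @return `occupancy_edges()`: the edge list data.frame.
#'   `occupancy_dot()`: a single DOT-language string for external graph
#'   renderers.
#' @export
occupancy_edges <- function(model) {
  stopifnot(inherits(model, "occupancy_model"))
  model$edges
}

#' @rdname occupancy_edges
#' @export
occupancy_dot <- function(model) {
  stopifnot(inherits(model, "occupancy_model"))
  lab <- function(s) gsub("[^A-Za-z0-9]", "_", s)
  lines <- c(
    sprintf("digraph occupancy_rq_%s {", gsub("-", "m", model$r_q)),
    sprintf('  %s [label="%s"];', vapply(model$states, lab, ""),
            model$states),
    if (nrow(model$edges)) {
      sprintf("  %s -> %s;", vapply(model$edges$from, lab, ""),
              vapply(model$edges$to, lab, ""))
    },
    "}"
  )
  paste(lines, collapse = "\n")
}
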