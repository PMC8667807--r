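# Independent oracles the implementation is checked against.

.ringcharge_aas <- function() strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]]

# Raw piecewise inequalities, written directly from their definitions and
# kept free of any package code paths.
oracle_verdict <- function(rq, qi, qr) {
  A <- if (abs(rq + qi) > 0) 1L else 0L
  B <- if (qi + abs(rq + qr) > qr) 1L else 0L
  A * B
}

# Exhaustive global-alignment score: enumerate every alignment of two short
# sequences recursively and take the maximum score.
oracle_align_score <- function(a, b, match = 1L, mismatch = -1L,
                               gap = -2L) {
  rec <- function(i, j) {
    if (i == 0L && j == 0L) return(0L)
    best <- -Inf
    if (i > 0L && j > 0L) {
      s <- if (substr(a, i, i) == substr(b, j, j)) match else mismatch
      best <- max(best, rec(i - 1L, j - 1L) + s)
    }
    if (i > 0L) best <- max(best, rec(i - 1L, j) + gap)
    if (j > 0L) best <- max(best, rec(i, j - 1L) + gap)
    best
  }
  as.integer(rec(nchar(a), nchar(b)))
}

# Brute-force occupancy classification by explicit path enumeration over the
# tiny state space (<= 4 states): no graph library, no SCC machinery.
oracle_classify <- function(rq, valences) {
  nm <- names(valences)
  states <- c("EMPTY", nm)
  qr_of <- function(s) if (s == "EMPTY") 0L else valences[[s]]
  edge <- function(s, i) oracle_verdict(rq, valences[[i]], qr_of(s)) == 1L

  succ <- lapply(states, function(s) nm[vapply(nm, edge, TRUE, s = s)])
  names(succ) <- states

  reach_from <- function(s0) {
    seen <- s0
    repeat {
      nxt <- unique(unlist(succ[seen]))
      new <- setdiff(nxt, seen)
      if (!length(new)) return(seen)
      seen <- c(seen, new)
    }
  }
  reachable <- reach_from("EMPTY")

  # state s is recurrent iff every state reachable from s can reach s back
  # (EMPTY has no incoming edges so it is recurrent only when it has no
  # successors at all)
  recurrent <- Filter(function(s) {
    down <- setdiff(reach_from(s), s)
    if (!length(down)) return(TRUE)
    all(vapply(down, function(t) s %in% reach_from(t), TRUE))
  }, reachable)

  # group recurrent states into terminal classes by mutual reachability
  classes <- list()
  left <- recurrent
  while (length(left)) {
    s <- left[[1]]
    cls <- Filter(function(t) {
      t %in% reach_from(s) && s %in% reach_from(t)
    }, recurrent)
    cls <- unique(c(s, unlist(cls)))
    classes <- c(classes, list(sort(cls)))
    left <- setdiff(left, cls)
  }

  res <- lapply(nm, function(i) {
    uncond <- all(vapply(states, edge, TRUE, i = i))
    steady <- all(vapply(unlist(classes), edge, TRUE, i = i))
    some <- any(vapply(states, edge, TRUE, i = i))
    c(unconditional = as.integer(uncond),
      steady_state = as.integer(steady),
      conditional = as.integer(some && !uncond))
  })
  names(res) <- nm
  res
}

# fixture FASTA written to a session tempfile, shared across tests
fixture_fasta_path <- local({
  path <- NULL
  function(seed = 1L) {
    if (is.null(path)) {
      path <<- tempfile(fileext = ".fasta")
      generate_sequences(fixture_spec(seed = seed), path = path)
    }
    path
  }
})
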