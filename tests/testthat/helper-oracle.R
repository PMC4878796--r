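# Independent brute-force oracle for the maximal-step semantics, written
# against the plain arc table only (no engine internals). Integer weights
# only: enumerate, by exhaustive depth-first search over reservation orders,
# every maximal firing multiset reachable from a marking.
#
# A transition is enabled when each input place holds at least its arc
# weight in unreserved tokens; reserving a firing subtracts the input
# weights; the multiset is maximal when nothing is enabled.

oracle_enumerate_firings <- function(net, marking = NULL) {
  arcs <- net$arcs
  stopifnot(all(arcs$den == 1L))
  if (is.null(marking)) marking <- net$marking
  marking <- marking[net$places]
  trs <- net$transitions
  ins <- lapply(trs, function(t) {
    a <- arcs[arcs$target == t, , drop = FALSE]
    list(place = a$source, w = a$num)
  })
  names(ins) <- trs
  seen <- new.env(parent = emptyenv())
  results <- new.env(parent = emptyenv())
  enabled_at <- function(avail) {
    which(vapply(ins, function(io) {
      length(io$place) > 0L && all(avail[io$place] >= io$w)
    }, logical(1)))
  }
  recurse <- function(avail, counts) {
    key <- paste(c(avail, counts), collapse = ",")
    if (!is.null(seen[[key]])) return(invisible())
    seen[[key]] <- TRUE
    en <- enabled_at(avail)
    if (!length(en)) {
      results[[paste(counts, collapse = ",")]] <- counts
      return(invisible())
    }
    for (ti in en) {
      io <- ins[[ti]]
      av2 <- avail
      av2[io$place] <- av2[io$place] - io$w
      c2 <- counts
      c2[ti] <- c2[ti] + 1L
      recurse(av2, c2)
    }
  }
  recurse(marking, stats::setNames(integer(length(trs)), trs))
  out <- as.list(results)
  unname(out)
}

firing_key <- function(counts) paste(counts, collapse = ",")

# Small fixture nets reused across test files ---------------------------

# source (weight-1) chain: src -> t -> snk
chain_net <- function(tokens = 4L, w_in = 1, w_out = 1) {
  petri_net(
    tibble::tibble(source = c("src", "t"), target = c("t", "snk"),
                   weight = c(w_in, w_out)),
    places = c("src", "snk"), transitions = "t",
    marking = c(src = as.integer(tokens))
  )
}

# two transitions competing for one shared input token
conflict_net <- function(tokens = 1L) {
  petri_net(
    tibble::tibble(source = c("p", "p", "ta", "tb"),
                   target = c("ta", "tb", "a", "b"),
                   weight = 1),
    places = c("p", "a", "b"), transitions = c("ta", "tb"),
    marking = c(p = as.integer(tokens))
  )
}
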