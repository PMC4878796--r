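# PNML interchange (ISO/IEC 15909-2 place/transition dialect).
#
# Node ids in the file are generated (p1..pN, t1..tM) because biological
# place names contain characters that are not legal XML ids; the human name
# travels in <name><text>. Arc inscriptions are written as exact decimal
# strings; fractional inscriptions (non-standard for stock PTNet tools, but
# documented) are parsed back into exact rationals, so write -> read is an
# identity on the net.

PNML_NS <- "http://www.pnml.org/version-2009/grammar/pnml"
PTNET_TYPE <- "http://www.pnml.org/version-2009/grammar/ptnet"

#' Write a Petri net to a PNML file
#'
#' Emits a place/transition PNML document with initial markings and arc
#' weights as inscriptions. Element order follows the net's stored order, so
#' writing the same net twice yields byte-identical files.
#'
#' @param net A valid [petri_net()].
#' @param path Output file path.
#' @return `path`, invisibly.
#' @seealso [read_pnml()]
#' @export
write_pnml <- function(net, path) {
  stop_if_invalid(net)
  doc <- xml2::xml_new_root("pnml", xmlns = PNML_NS)
  netel <- xml2::xml_add_child(doc, "net", id = "net1", type = PTNET_TYPE)
  page <- xml2::xml_add_child(netel, "page", id = "page1")
  pid <- stats::setNames(paste0("p", seq_along(net$places)), net$places)
  tid <- stats::setNames(paste0("t", seq_along(net$transitions)),
                         net$transitions)
  for (p in net$places) {
    el <- xml2::xml_add_child(page, "place", id = pid[[p]])
    nm <- xml2::xml_add_child(el, "name")
    xml2::xml_add_child(nm, "text", p)
    mk <- xml2::xml_add_child(el, "initialMarking")
    xml2::xml_add_child(mk, "text", as.character(net$marking[[p]]))
  }
  for (t in net$transitions) {
    el <- xml2::xml_add_child(page, "transition", id = tid[[t]])
    nm <- xml2::xml_add_child(el, "name")
    xml2::xml_add_child(nm, "text", t)
  }
  ids <- c(pid, tid)
  a <- net$arcs
  for (i in seq_len(nrow(a))) {
    el <- xml2::xml_add_child(page, "arc", id = paste0("a", i),
                              source = ids[[a$source[i]]],
                              target = ids[[a$target[i]]])
    ins <- xml2::xml_add_child(el, "inscription")
    xml2::xml_add_child(ins, "text", weight_label(a$num[i], a$den[i]))
  }
  xml2::write_xml(doc, path)
  invisible(path)
}

#' Read a Petri net from a PNML file
#'
#' Accepts integer and decimal arc inscriptions (decimals are parsed exactly
#' into rationals, e.g. `"0.15"` becomes 3/20) and `"p/q"` fraction strings.
#' An arc whose inscription is 0 is taken as deliberate and recorded in the
#' net's `zero_ok` set. The returned net passes [validate_net()]; structural
#' problems in the file (unknown node references, place -> place arcs) raise
#' an error naming the offending element id.
#'
#' @param path Path to a PNML file.
#' @return A valid [petri_net()].
#' @export
read_pnml <- function(path) {
  doc <- xml2::read_xml(path)
  xml2::xml_ns_strip(doc)
  name_of <- function(el, fallback) {
    txt <- xml2::xml_find_first(el, "./name/text")
    if (inherits(txt, "xml_missing")) fallback else xml2::xml_text(txt)
  }
  pels <- xml2::xml_find_all(doc, ".//place")
  tels <- xml2::xml_find_all(doc, ".//transition")
  pids <- xml2::xml_attr(pels, "id")
  tids <- xml2::xml_attr(tels, "id")
  places <- vapply(seq_along(pels), function(i) {
    name_of(pels[[i]], pids[i])
  }, character(1))
  transitions <- vapply(seq_along(tels), function(i) {
    name_of(tels[[i]], tids[i])
  }, character(1))
  marking <- vapply(pels, function(el) {
    txt <- xml2::xml_find_first(el, "./initialMarking/text")
    if (inherits(txt, "xml_missing")) 0L else as.integer(xml2::xml_text(txt))
  }, integer(1))
  id2name <- stats::setNames(c(places, transitions), c(pids, tids))
  is_place <- stats::setNames(c(rep(TRUE, length(pids)),
                                rep(FALSE, length(tids))), c(pids, tids))
  aels <- xml2::xml_find_all(doc, ".//arc")
  src <- tgt <- character(length(aels))
  wt <- character(length(aels))
  zero_ok <- character()
  for (i in seq_along(aels)) {
    el <- aels[[i]]
    aid <- xml2::xml_attr(el, "id")
    s <- xml2::xml_attr(el, "source")
    t <- xml2::xml_attr(el, "target")
    for (ref in c(s, t)) {
      if (!ref %in% names(id2name)) {
        stop("arc '", aid, "' references unknown node '", ref, "'")
      }
    }
    if (is_place[[s]] == is_place[[t]]) {
      stop("arc '", aid, "' is not bipartite (joins two ",
           if (is_place[[s]]) "places" else "transitions", ")")
    }
    src[i] <- id2name[[s]]
    tgt[i] <- id2name[[t]]
    ins <- xml2::xml_find_first(el, "./inscription/text")
    wt[i] <- if (inherits(ins, "xml_missing")) "1" else xml2::xml_text(ins)
    if (parse_weight(wt[i])$num == 0L) {
      zero_ok <- c(zero_ok, arc_key(src[i], tgt[i]))
    }
  }
  net <- petri_net(
    tibble::tibble(source = src, target = tgt, weight = wt),
    places = places, transitions = transitions,
    marking = stats::setNames(marking, places), zero_ok = zero_ok
  )
  stop_if_invalid(net)
  net
}

#' Export a trace or summary to tidy CSV
#'
#' Traces are written long (`step`, `place`, `tokens`); ensemble summaries
#' and sweeps keep their tidy columns. Floating summaries are printed at 6
#' significant digits.
#'
#' @param x A `petri_trace`, `ensemble_summary` or `wnt_sweep`.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_result_csv <- function(x, path) {
  d <- if (inherits(x, "petri_trace")) tidy(x) else
    tibble::as_tibble(as.data.frame(unclass(x)))
  num <- vapply(d, is.double, logical(1))
  d[num] <- lapply(d[num], signif, digits = 6)
  utils::write.csv(d, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
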