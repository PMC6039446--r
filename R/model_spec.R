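#' Construct a permeation model specification
#'
#' A permeation model is a strongly connected directed graph of selectivity
#' filter ion configurations.  Every edge carries a named rate parameter and
#' a kind: `plain` (condition-independent), `bind_internal` /
#' `bind_external` (rate proportional to the internal/external K+ activity)
#' or `eyring` (voltage-dependent over an Eyring barrier; the two directions
#' of a barrier share one `eyring_group`).  A designated transport cycle is
#' the closed walk whose forward traversal moves one elementary charge
#' outward.
#'
#' @param name model identifier.
#' @param states character vector of state labels (ordered).
#' @param occupancy character vector, human-readable filter occupancy per
#'   state (which of S0--S4 and the pore mouths hold an ion).
#' @param edges data.frame with columns `from`, `to`, `param`, `kind` and
#'   optionally `eyring_group` (NA for non-Eyring edges).
#' @param transport_cycle character vector of state labels; the closing edge
#'   from the last back to the first state is implied.
#' @param note optional free-text annotation (e.g. marking a spec as
#'   approximate).
#' @return An object of class `perm_model`.
#' @seealso [shipped_model()] for the bundled model specifications.
#' @export
perm_model <- function(name, states, occupancy, edges, transport_cycle,
                       note = NULL) {
  stopifnot(is.character(states), length(states) >= 2,
            !anyDuplicated(states), is.data.frame(edges))
  if (length(occupancy) != length(states)) {
    stop("`occupancy` must annotate every state")
  }
  req <- c("from", "to", "param", "kind")
  if (!all(req %in% names(edges))) {
    stop("edges need columns: ", paste(req, collapse = ", "))
  }
  if (is.null(edges$eyring_group)) edges$eyring_group <- NA_character_
  edges <- data.frame(lapply(edges[c(req, "eyring_group")], as.character),
                      stringsAsFactors = FALSE)
  kinds <- c("plain", "bind_internal", "bind_external", "eyring")
  if (!all(edges$kind %in% kinds)) {
    stop("edge kind must be one of: ", paste(kinds, collapse = ", "))
  }
  if (!all(c(edges$from, edges$to) %in% states)) {
    stop("edge endpoints must be model states")
  }
  if (anyDuplicated(edges[c("from", "to")])) {
    stop("duplicate directed edge")
  }
  if (anyDuplicated(edges$param)) stop("duplicate edge parameter name")

  # every edge must have a reverse edge
  key <- paste(edges$from, edges$to, sep = "->")
  rkey <- paste(edges$to, edges$from, sep = "->")
  if (!all(rkey %in% key)) {
    stop("missing reverse edge for: ", paste(key[!(rkey %in% key)],
                                             collapse = ", "))
  }

  # strong connectivity by directed reachability from the first state
  reach <- function(adj, start, n) {
    seen <- rep(FALSE, n); seen[start] <- TRUE; frontier <- start
    while (length(frontier)) {
      nxt <- unique(unlist(adj[frontier]))
      nxt <- nxt[!seen[nxt]]
      seen[nxt] <- TRUE; frontier <- nxt
    }
    seen
  }
  n <- length(states)
  fi <- match(edges$from, states); ti <- match(edges$to, states)
  adj_f <- split(ti, factor(fi, levels = seq_len(n)))
  adj_b <- split(fi, factor(ti, levels = seq_len(n)))
  if (!all(reach(adj_f, 1L, n)) || !all(reach(adj_b, 1L, n))) {
    stop("model graph is not strongly connected")
  }

  # transport cycle: closed walk over existing edges
  tc <- as.character(transport_cycle)
  if (length(tc) && tc[1] == tc[length(tc)]) tc <- tc[-length(tc)]
  if (!all(tc %in% states) || length(tc) < 2) {
    stop("transport_cycle must list model states")
  }
  cyc_from <- tc
  cyc_to <- c(tc[-1], tc[1])
  cyc_key <- paste(cyc_from, cyc_to, sep = "->")
  if (!all(cyc_key %in% key)) {
    stop("transport_cycle uses non-existent edges: ",
         paste(setdiff(cyc_key, key), collapse = ", "))
  }
  edges$cycle_forward <- key %in% cyc_key
  edges$cycle_backward <- key %in% paste(cyc_to, cyc_from, sep = "->")

  # Eyring groups: exactly one forward/backward pair each, both on the cycle
  ey <- edges[edges$kind == "eyring", ]
  if (nrow(ey)) {
    if (any(is.na(ey$eyring_group))) {
      stop("eyring edges must carry an eyring_group")
    }
    for (g in unique(ey$eyring_group)) {
      pair <- ey[ey$eyring_group == g, ]
      if (nrow(pair) != 2 || !identical(sort(paste(pair$from, pair$to)),
                                        sort(paste(pair$to, pair$from)))) {
        stop("eyring_group '", g,
             "' must contain exactly one edge and its reverse")
      }
      if (!any(pair$cycle_forward)) {
        stop("eyring_group '", g, "' must lie on the transport cycle")
      }
    }
    if (any(!is.na(edges$eyring_group) & edges$kind != "eyring")) {
      stop("eyring_group set on a non-eyring edge")
    }
  }

  structure(
    list(name = as.character(name), states = states,
         occupancy = as.character(occupancy), edges = edges,
         transport_cycle = tc, note = note),
    class = "perm_model"
  )
}

#' @export
print.perm_model <- function(x, ...) {
  cat("Permeation model '", x$name, "': ", length(x$states), " states, ",
      nrow(x$edges), " directed edges\n", sep = "")
  cat("  cycle:", paste(c(x$transport_cycle, x$transport_cycle[1]),
                        collapse = " -> "), "\n")
  ey <- unique(stats::na.omit(x$edges$eyring_group))
  if (length(ey)) cat("  Eyring groups:", paste(ey, collapse = ", "), "\n")
  if (!is.null(x$note)) cat("  note:", x$note, "\n")
  invisible(x)
}

#' Read / write a permeation model specification (JSON)
#'
#' @param path file path of a model JSON document.
#' @return [read_model_spec()] returns a validated `perm_model`;
#'   [write_model_spec()] invisibly returns `path`.
#' @export
read_model_spec <- function(path) {
  doc <- jsonlite::read_json(path, simplifyVector = TRUE)
  for (f in c("name", "states", "edges", "transport_cycle")) {
    if (is.null(doc[[f]])) stop("model JSON lacks field '", f, "'")
  }
  perm_model(
    name = doc$name,
    states = as.character(doc$states$label),
    occupancy = as.character(doc$states$occupancy),
    edges = as.data.frame(doc$edges),
    transport_cycle = doc$transport_cycle,
    note = doc$note
  )
}

#' @param model a `perm_model`.
#' @rdname read_model_spec
#' @export
write_model_spec <- function(model, path) {
  stopifnot(inherits(model, "perm_model"))
  ed <- model$edges[c("from", "to", "param", "kind", "eyring_group")]
  doc <- list(
    name = model$name,
    states = data.frame(label = model$states, occupancy = model$occupancy),
    edges = ed,
    transport_cycle = model$transport_cycle
  )
  if (!is.null(model$note)) doc$note <- model$note
  jsonlite::write_json(doc, path, auto_unbox = TRUE, pretty = TRUE,
                       na = "null", digits = NA)
  invisible(path)
}

#' Bundled permeation model specifications
#'
#' Three model topologies are shipped as JSON documents:
#' * `"five_state_roux"` -- the 5-state ion hopping cycle with internal
#'   binding, two Eyring translocation steps and an outer-mouth state
#'   between S0 occupancy and external release;
#' * `"four_state"` -- the same cycle with the outer-mouth state removed
#'   (external release directly from the S0-occupied configuration);
#' * `"hard_knock_on"` -- a direct knock-on cycle with two adjacent
#'   voltage-dependent concerted translocation steps (an approximate
#'   topology; see the `note` field of the spec).
#'
#' @param name one of `"five_state_roux"`, `"four_state"`,
#'   `"hard_knock_on"`.
#' @return A validated `perm_model`.
#' @examples
#' shipped_model("five_state_roux")
#' @export
shipped_model <- function(name = c("five_state_roux", "four_state",
                                   "hard_knock_on")) {
  name <- match.arg(name)
  path <- system.file("extdata", "models", paste0(name, ".json"),
                      package = "permgate")
  if (path == "") stop("bundled model spec not found: ", name)
  read_model_spec(path)
}
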