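#' Construct a finite-state channel gating scheme
#'
#' A gating scheme is a continuous-time Markov model of channel
#' conformations: a set of named states, each carrying a conducting
#' weight (1 for the open state, 0 for inactivated states), and a set
#' of directed transitions with first-order rate constants.
#'
#' @param states Character vector of unique state labels.
#' @param conducting Numeric vector of conducting weights, one per state
#'   (typically 1 for the open state, 0 otherwise).
#' @param transitions Data frame with columns `from`, `to`, `rate`
#'   (rates in s^-1). Self-transitions are not allowed.
#' @return An object of class `gating_scheme`.
#' @examples
#' gating_scheme(
#'   states = c("O", "Ia"), conducting = c(1, 0),
#'   transitions = data.frame(from = c("O", "Ia"), to = c("Ia", "O"),
#'                            rate = c(118.3, 48.3))
#' )
#' @export
gating_scheme <- function(states, conducting, transitions) {
  stopifnot(is.character(states), length(states) >= 1)
  if (anyDuplicated(states)) {
    stop("duplicate state labels: ",
         paste(unique(states[duplicated(states)]), collapse = ", "))
  }
  if (length(conducting) != length(states) || any(conducting < 0)) {
    stop("`conducting` must be a non-negative weight per state")
  }
  if (all(conducting == 0)) {
    stop("at least one state must have a nonzero conducting weight")
  }
  transitions <- tibble::as_tibble(transitions)
  if (nrow(transitions) > 0) {
    stopifnot(all(c("from", "to", "rate") %in% names(transitions)))
    unknown <- setdiff(c(transitions$from, transitions$to), states)
    if (length(unknown) > 0) {
      stop("transition references unknown state(s): ",
           paste(unique(unknown), collapse = ", "))
    }
    if (any(transitions$from == transitions$to)) {
      stop("self-transitions are not allowed")
    }
    if (any(transitions$rate < 0) || any(!is.finite(transitions$rate))) {
      stop("all rates must be finite and >= 0")
    }
  } else {
    transitions <- tibble::tibble(from = character(), to = character(),
                                  rate = numeric())
  }
  scheme <- structure(
    list(states = states,
         conducting = as.numeric(conducting),
         transitions = transitions),
    class = "gating_scheme")
  if (nrow(transitions) > 0 && !is_connected(scheme)) {
    stop("the transition graph is not connected; components: ",
         format_components(scheme))
  }
  scheme
}

# connected components of the undirected transition graph
scheme_components <- function(scheme) {
  n <- length(scheme$states)
  idx <- stats::setNames(seq_len(n), scheme$states)
  adj <- matrix(FALSE, n, n)
  tr <- scheme$transitions
  pos <- tr$rate > 0
  if (any(pos)) {
    i <- idx[tr$from[pos]]; j <- idx[tr$to[pos]]
    adj[cbind(i, j)] <- TRUE
    adj[cbind(j, i)] <- TRUE
  }
  comp <- integer(n)
  cur <- 0L
  for (s in seq_len(n)) {
    if (comp[s] == 0L) {
      cur <- cur + 1L
      frontier <- s
      comp[s] <- cur
      while (length(frontier) > 0) {
        nxt <- which(adj[frontier[1], ] & comp == 0L)
        comp[nxt] <- cur
        frontier <- c(frontier[-1], nxt)
      }
    }
  }
  split(scheme$states, comp)
}

is_connected <- function(scheme) length(scheme_components(scheme)) == 1L

format_components <- function(scheme) {
  comps <- scheme_components(scheme)
  paste(vapply(comps, function(x) paste0("{", paste(x, collapse = ","), "}"),
               character(1)), collapse = " ")
}

#' @export
print.gating_scheme <- function(x, ...) {
  cat("<gating_scheme> ", length(x$states), " states: ",
      paste0(x$states, ifelse(x$conducting > 0, "*", ""), collapse = " "),
      "  (* = conducting)\n", sep = "")
  print(x$transitions, ...)
  invisible(x)
}

#' Build the generator (Q) matrix of a gating scheme
#'
#' Row convention: off-diagonal entry (i, j) holds the rate from state i
#' to state j in s^-1; each diagonal entry is minus its row sum, so every
#' row sums to zero. Occupancy row vectors evolve as dp/dt = p Q.
#'
#' @param scheme A [gating_scheme()].
#' @return Square numeric matrix with state labels as dimnames.
#' @export
build_generator <- function(scheme) {
  stopifnot(inherits(scheme, "gating_scheme"))
  n <- length(scheme$states)
  G <- matrix(0, n, n, dimnames = list(scheme$states, scheme$states))
  tr <- scheme$transitions
  if (nrow(tr) > 0) {
    for (k in seq_len(nrow(tr))) {
      G[tr$from[k], tr$to[k]] <- G[tr$from[k], tr$to[k]] + tr$rate[k]
    }
  }
  diag(G) <- 0
  diag(G) <- -rowSums(G)
  G
}

assert_generator <- function(G) {
  stopifnot(is.matrix(G), nrow(G) == ncol(G))
  offdiag <- G; diag(offdiag) <- 0
  if (any(offdiag < 0)) stop("generator has negative off-diagonal entries")
  scale <- max(abs(G), 1)
  if (any(abs(rowSums(G)) > 1e-12 * scale)) {
    stop("generator rows do not sum to zero")
  }
  invisible(G)
}

#' Serialize a gating scheme to JSON
#'
#' The document has the form
#' `{"states":[{"name":"O","conducting":1},...],
#'   "transitions":[{"from":"O","to":"Ia","rate":30.0},...]}` with rates
#' in s^-1.
#'
#' @param scheme A [gating_scheme()].
#' @param path Optional file path; if `NULL` the JSON string is returned.
#' @return JSON string (invisibly, if written to a file).
#' @export
scheme_to_json <- function(scheme, path = NULL) {
  stopifnot(inherits(scheme, "gating_scheme"))
  doc <- list(
    states = purrr::map2(scheme$states, scheme$conducting,
                         function(s, w) list(name = s, conducting = w)),
    transitions = purrr::pmap(scheme$transitions,
                              function(from, to, rate)
                                list(from = from, to = to, rate = rate)))
  js <- jsonlite::toJSON(doc, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  if (is.null(path)) return(as.character(js))
  writeLines(js, path)
  invisible(as.character(js))
}

#' Read a gating scheme from its JSON serialization
#'
#' @param json JSON string or path to a JSON file (see [scheme_to_json()]).
#' @return A [gating_scheme()].
#' @export
scheme_from_json <- function(json) {
  doc <- jsonlite::fromJSON(json, simplifyDataFrame = TRUE)
  tr <- if (length(doc$transitions) > 0) {
    tibble::as_tibble(doc$transitions)
  } else {
    tibble::tibble(from = character(), to = character(), rate = numeric())
  }
  gating_scheme(states = doc$states$name,
                conducting = doc$states$conducting,
                transitions = tr)
}
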