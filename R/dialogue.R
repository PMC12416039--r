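# Dialogue management over a directed acyclic topic network.
#
# Long medical-history intakes need a controller deciding whether to stay on
# the current topic (allowing digressions), redirect a digressing patient,
# or advance. Topics group schema events (demographics, antidepressant
# history, comorbidities, ...); edges are derived from the knowledgebase —
# cross-topic dependencies in the imputation network and co-retention in
# drug models — and oriented by a fixed topic priority so the graph is
# acyclic by construction.

#' Derive a topic network from the knowledgebase
#'
#' Edge weight from topic i to topic j accumulates (a) the absolute
#' coefficients of topic-i events predicting topic-j events in the
#' imputation network, and (b) one unit per cross-topic pair of events
#' co-retained in a drug model. Edges are oriented from the
#' higher-priority (earlier) topic to the lower, and kept when their weight
#' exceeds `threshold`.
#'
#' @param kb a `knowledgebase`.
#' @param topic_assignment named character vector event id → topic name;
#'   every schema event must be assigned to exactly one topic.
#' @param priority character vector of topic names, highest priority first;
#'   the first topic is the designated start and has no incoming edges.
#' @param threshold minimum accumulated weight for an edge (default 0).
#' @return object of class `topic_network`: `topics`, `priority`, `edges`
#'   (data.frame from/to/weight), `start`, `assignment`.
#' @export
build_topic_network <- function(kb, topic_assignment, priority,
                                threshold = 0) {
  missing_ev <- setdiff(kb$schema$event_id, names(topic_assignment))
  if (length(missing_ev)) {
    stop("events missing a topic assignment: ",
         paste(missing_ev, collapse = ", "))
  }
  if (!setequal(priority, unique(topic_assignment))) {
    stop("priority must list exactly the assigned topics")
  }
  rank <- stats::setNames(seq_along(priority), priority)
  w <- matrix(0, length(priority), length(priority),
              dimnames = list(priority, priority))
  orient <- function(a, b, weight) {
    if (rank[[a]] == rank[[b]]) return()
    hi <- if (rank[[a]] < rank[[b]]) a else b
    lo <- if (rank[[a]] < rank[[b]]) b else a
    w[hi, lo] <<- w[hi, lo] + weight
  }
  for (m in kb$imputation) {
    tj <- topic_assignment[[m$target]]
    for (e in names(m$coefficients)) {
      ti <- topic_assignment[[e]]
      if (ti != tj) orient(ti, tj, abs(m$coefficients[[e]]))
    }
  }
  for (dm in kb$general) {
    evs <- names(dm$coefficients)[dm$coefficients != 0]
    tp <- topic_assignment[evs]
    if (length(evs) >= 2) {
      pairs <- utils::combn(seq_along(evs), 2)
      for (k in seq_len(ncol(pairs))) {
        a <- tp[[pairs[1, k]]]; b <- tp[[pairs[2, k]]]
        if (a != b) orient(a, b, 1)
      }
    }
  }
  idx <- which(w > threshold, arr.ind = TRUE)
  edges <- data.frame(from = rownames(w)[idx[, 1]],
                      to = colnames(w)[idx[, 2]],
                      weight = w[idx], stringsAsFactors = FALSE)
  edges <- edges[order(edges$from, edges$to), , drop = FALSE]
  rownames(edges) <- NULL
  g <- igraph::graph_from_data_frame(
    if (nrow(edges)) edges[c("from", "to")] else
      data.frame(from = character(0), to = character(0)),
    directed = TRUE, vertices = priority)
  if (!igraph::is_dag(g)) stop("topic network is not acyclic")  # defensive
  structure(list(topics = priority, priority = priority, edges = edges,
                 start = priority[1], assignment = topic_assignment),
            class = "topic_network")
}

#' Start a dialogue
#'
#' @param network a [build_topic_network()] result.
#' @param per_topic_cap maximum turns spent on one topic before advancing
#'   (default 6).
#' @return object of class `dialogue_state`: `current`, `status` (named
#'   vector over topics: unvisited/open/resolved), `digression`, `turns`
#'   (in current topic), `decisions` (total).
#' @export
dialogue_state <- function(network, per_topic_cap = 6L) {
  status <- stats::setNames(rep("unvisited", length(network$topics)),
                            network$topics)
  status[network$start] <- "open"
  structure(list(current = network$start, status = status,
                 digression = FALSE, turns = 0L, decisions = 0L,
                 per_topic_cap = as.integer(per_topic_cap)),
            class = "dialogue_state")
}

#' Flag a digression on the current turn
#' @param state a `dialogue_state`.
#' @return updated state.
#' @export
note_digression <- function(state) { state$digression <- TRUE; state }

#' Mark the current topic's events as covered
#' @param state a `dialogue_state`.
#' @return updated state; the controller will advance on the next decision.
#' @export
resolve_topic <- function(state) {
  state$status[state$current] <- "resolved"
  state
}

#' Decide the next dialogue move
#'
#' Precedence: a flagged digression always redirects back to the current
#' topic; an open current topic below the per-topic turn cap stays;
#' otherwise the dialogue advances to the highest-priority unvisited topic
#' whose predecessors in the network are all resolved; when every topic is
#' resolved the dialogue ends. Visit order is therefore always a topological
#' order of the network, and every dialogue terminates within
#' `topics × per_topic_cap` decisions.
#'
#' @param state a `dialogue_state`.
#' @param network a `topic_network`.
#' @return list with updated `state` and `action`: one of
#'   `list(type = "redirect", topic = )`, `list(type = "stay", topic = )`,
#'   `list(type = "advance", topic = )`, `list(type = "end")`.
#' @export
next_topic <- function(state, network) {
  state$decisions <- state$decisions + 1L
  if (state$digression) {
    state$digression <- FALSE
    state$turns <- state$turns + 1L
    return(list(state = state,
                action = list(type = "redirect", topic = state$current)))
  }
  if (state$status[state$current] == "open" &&
      state$turns < state$per_topic_cap) {
    state$turns <- state$turns + 1L
    return(list(state = state,
                action = list(type = "stay", topic = state$current)))
  }
  # current topic exhausted (resolved or capped): close it and advance
  state$status[state$current] <- "resolved"
  preds_resolved <- function(tp) {
    preds <- network$edges$from[network$edges$to == tp]
    all(state$status[preds] == "resolved")
  }
  for (tp in network$priority) {
    if (state$status[tp] == "unvisited" && preds_resolved(tp)) {
      state$current <- tp
      state$status[tp] <- "open"
      state$turns <- 1L
      return(list(state = state,
                  action = list(type = "advance", topic = tp)))
    }
  }
  list(state = state, action = list(type = "end"))
}

#' Export a topic network in DOT format
#'
#' @param network a `topic_network`.
#' @return single character string of Graphviz DOT source.
#' @export
topic_network_dot <- function(network) {
  lines <- c("digraph topics {",
             sprintf('  "%s";', network$topics),
             sprintf('  "%s" -> "%s" [label="%.3g"];',
                     network$edges$from, network$edges$to,
                     network$edges$weight),
             "}")
  paste(lines, collapse = "\n")
}
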