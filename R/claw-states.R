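#' Encode / decode CLAW network states
#'
#' A network state is the binary activity pattern of the N = 10
#' state-defining streams, mapped bijectively to an integer index in
#' \eqn{[0, 2^N - 1]} by its base-2 representation (first bit most
#' significant, in the declared stream order).
#'
#' @param bits integer 0/1 vector of length N.
#' @param k integer state index.
#' @param n_bits number of bits N (default 10).
#' @return \code{encode_state}: the integer index; \code{decode_state}: the
#'   0/1 bit vector.
#' @export
encode_state <- function(bits) {
  if (!is.numeric(bits) && !is.logical(bits))
    stop("bits must be numeric or logical")
  bits <- as.integer(bits)
  if (any(!bits %in% c(0L, 1L))) stop("bits must be 0 or 1")
  n <- length(bits)
  as.integer(sum(bits * 2^((n - 1):0)))
}

#' @rdname encode_state
#' @export
decode_state <- function(k, n_bits = 10) {
  if (k < 0 || k > 2^n_bits - 1) stop("state index out of range")
  as.integer(bitwAnd(k %/% 2^((n_bits - 1):0), 1L))
}

#' Collapse a binarized trial into a state sequence
#'
#' Encodes each time bin of a binarized trial as a state index and merges
#' consecutive identical states, preserving dwell counts.  The sum of dwell
#' counts equals the number of bins.
#'
#' @param binary integer 0/1 matrix [bin x state stream], already truncated
#'   at the decision bin.
#' @return A \code{claw_sequence}: list with \code{state} (indices) and
#'   \code{dwell} (bins), plus \code{n_bins}.
#' @export
state_sequence <- function(binary) {
  n <- nrow(binary)
  if (n == 0L)
    return(structure(list(state = integer(0), dwell = integer(0),
                          n_bins = 0L), class = "claw_sequence"))
  idx <- apply(binary, 1, encode_state)
  r <- rle(idx)
  structure(list(state = r$values, dwell = r$lengths, n_bins = n),
            class = "claw_sequence")
}

# per-bin expansion of a collapsed sequence
expand_sequence <- function(seq) rep(seq$state, seq$dwell)

#' Empirical state transition matrix
#'
#' Pools per-bin transitions (including self-transitions, i.e. dwell loops)
#' across state sequences into visit counts and row-normalized transition
#' probabilities.  Rows with at least one outgoing transition sum to 1;
#' unvisited rows are all zero.
#'
#' @param sequences list of \code{claw_sequence}.
#' @param n_states size of the state space (default \eqn{2^{10}}).
#' @return A \code{claw_tm}: list with sparse-style triplet data frame
#'   \code{transitions} (\code{from}, \code{to}, \code{count}, \code{prob}),
#'   \code{visits} (named count per visited state) and \code{n_states}.
#' @export
transition_matrix <- function(sequences, n_states = 1024L) {
  if (length(sequences) == 0L) stop("no sequences supplied")
  from <- integer(0); to <- integer(0)
  visits <- integer(0)
  for (s in sequences) {
    bins <- expand_sequence(s)
    v <- table(bins)
    visits <- c(visits, stats::setNames(as.integer(v), names(v)))
    if (length(bins) >= 2L) {
      from <- c(from, bins[-length(bins)])
      to <- c(to, bins[-1L])
    }
  }
  visits <- tapply(visits, names(visits), sum)
  key <- paste(from, to)
  agg <- table(key)
  parts <- strsplit(names(agg), " ", fixed = TRUE)
  tr <- data.frame(
    from = as.integer(vapply(parts, `[`, "", 1L)),
    to = as.integer(vapply(parts, `[`, "", 2L)),
    count = as.integer(agg),
    stringsAsFactors = FALSE)
  out_count <- tapply(tr$count, tr$from, sum)
  tr$prob <- tr$count / as.numeric(out_count[as.character(tr$from)])
  tr <- tr[order(tr$from, tr$to), ]
  rownames(tr) <- NULL
  structure(list(transitions = tr,
                 visits = stats::setNames(as.integer(visits), names(visits)),
                 n_states = as.integer(n_states)),
            class = "claw_tm")
}

#' @export
print.claw_tm <- function(x, ...) {
  cat(sprintf("CLAW transition matrix: %d visited states, %d edges (of %d^2)\n",
              length(x$visits), nrow(x$transitions), x$n_states))
  invisible(x)
}

# row of transition probabilities out of state `from` (named by target)
tm_row <- function(tm, from) {
  sel <- tm$transitions$from == from
  stats::setNames(tm$transitions$prob[sel], tm$transitions$to[sel])
}

#' Extract the high-probability CLAW graph
#'
#' Keeps states visited at least \code{min_visits} times and transitions
#' with empirical probability at least \code{min_edge_prob}, and returns the
#' resulting directed graph of dominant decision paths.
#'
#' @param tm a \code{claw_tm}.
#' @param min_edge_prob edge probability threshold in (0, 1].
#' @param min_visits minimum state visit count (>= 1).
#' @return A \code{claw_graph}: list with \code{states} (kept indices),
#'   \code{edges} (triplet data frame) and an \pkg{igraph} \code{graph}.
#' @export
extract_claw <- function(tm, min_edge_prob = 0.01, min_visits = 20) {
  stopifnot(min_edge_prob > 0, min_edge_prob <= 1, min_visits >= 1)
  keep <- as.integer(names(tm$visits)[tm$visits >= min_visits])
  e <- tm$transitions
  e <- e[e$from %in% keep & e$to %in% keep & e$prob >= min_edge_prob, ]
  g <- igraph::graph_from_data_frame(
    data.frame(from = as.character(e$from), to = as.character(e$to)),
    directed = TRUE,
    vertices = data.frame(name = as.character(keep)))
  igraph::E(g)$prob <- e$prob
  igraph::E(g)$count <- e$count
  structure(list(states = keep, edges = e, graph = g), class = "claw_graph")
}

#' @export
print.claw_graph <- function(x, ...) {
  cat(sprintf("CLAW graph: %d states, %d edges\n",
              length(x$states), nrow(x$edges)))
  invisible(x)
}
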