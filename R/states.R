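#' Labor-market state space
#'
#' The model distinguishes seven mutually exclusive labor-market states:
#' four recurrent states (\code{work}, \code{sickness_absence},
#' \code{unemployment}, \code{temporary_out}) that an employee can enter and
#' leave repeatedly, and three absorbing states (\code{retirement},
#' \code{disability_pension}, \code{death}) that terminate follow-up.
#' Every recurrent state has an arrow to each of the six other states, giving
#' 4 x 6 = 24 permitted transitions.
#'
#' @return \code{elma_states()} returns the character vector of the seven
#'   state names in canonical order.
#' @export
elma_states <- function() {
  c("work", "sickness_absence", "unemployment", "temporary_out",
    "retirement", "disability_pension", "death")
}

#' @rdname elma_states
#' @return \code{recurrent_states()} / \code{absorbing_states()} return the
#'   corresponding subsets.
#' @export
recurrent_states <- function() elma_states()[1:4]

#' @rdname elma_states
#' @export
absorbing_states <- function() elma_states()[5:7]

#' @rdname elma_states
#' @return \code{permitted_transitions()} returns a data.frame with columns
#'   \code{from}, \code{to} (state names) and \code{trans} (1..24), one row
#'   per permitted arrow, ordered by origin then destination.
#' @export
permitted_transitions <- function() {
  st <- elma_states()
  from <- rep(recurrent_states(), each = 6L)
  to <- unlist(lapply(recurrent_states(), function(h) setdiff(st, h)),
               use.names = FALSE)
  data.frame(from = from, to = to, trans = seq_along(from),
             stringsAsFactors = FALSE)
}

# integer codes used internally; order matches elma_states()
state_code <- function(state) {
  i <- match(state, elma_states())
  if (anyNA(i)) stop("unknown state(s): ",
                     paste(unique(state[is.na(i)]), collapse = ", "))
  i
}

# absorbing priority when simultaneous records compete: death strongest
absorbing_priority <- function() {
  c(death = 3L, disability_pension = 2L, retirement = 1L)
}
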