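# EQ-5D-5L health states and value sets.
#
# A health state is a 5-character code over the dimensions mobility (mo),
# self-care (sc), usual activities (ua), pain/discomfort (pd) and
# anxiety/depression (ad), each at a severity level 1 (no problems) to 5
# (extreme problems): "11111" is full health. A value set maps each of the
# 5^5 = 3125 states to a utility index anchored at 1 for full health; values
# below 0 represent states rated worse than dead.

eq5d_dimensions <- c("mo", "sc", "ua", "pd", "ad")

#' Enumerate all EQ-5D-5L health-state codes
#'
#' @return Character vector of the 3125 five-digit state codes, "11111" first.
#' @export
all_health_states <- function() {
  g <- expand.grid(ad = 1:5, pd = 1:5, ua = 1:5, sc = 1:5, mo = 1:5)
  paste0(g$mo, g$sc, g$ua, g$pd, g$ad)
}

#' Build a health-state code from dimension levels
#'
#' @param mo,sc,ua,pd,ad Integer severity levels in 1..5 for mobility,
#'   self-care, usual activities, pain/discomfort, anxiety/depression.
#' @return Character state code, e.g. \code{"21345"}.
#' @export
health_state <- function(mo, sc, ua, pd, ad) {
  lv <- cbind(mo, sc, ua, pd, ad)
  if (any(is.na(lv)) || any(lv != as.integer(lv)) || any(lv < 1L) || any(lv > 5L))
    stop("dimension levels must be integers in 1..5", call. = FALSE)
  apply(lv, 1L, paste0, collapse = "")
}

#' Split health-state codes into dimension levels
#'
#' @param state Character vector of 5-digit state codes.
#' @return Integer matrix with one row per state and columns
#'   \code{mo, sc, ua, pd, ad}.
#' @export
state_levels <- function(state) {
  state <- as.character(state)
  bad <- is.na(state) | !grepl("^[1-5]{5}$", state)
  if (any(bad))
    stop("malformed health-state code(s): ",
         paste(unique(state[bad]), collapse = ", "), call. = FALSE)
  m <- matrix(as.integer(unlist(strsplit(state, ""), use.names = FALSE)),
              ncol = 5L, byrow = TRUE)
  colnames(m) <- eq5d_dimensions
  m
}

#' Construct an EQ-5D-5L value set
#'
#' A value set may be supplied either as a full lookup (one index value per
#' state) or as additive disutility coefficients: the index of a state is
#' then \eqn{1 - \sum_d c_{d,\ell_d}} where \eqn{c_{d,\ell}} is the
#' decrement for dimension \eqn{d} at level \eqn{\ell} (level 1 carries no
#' decrement). Either way the object stores the fully expanded 3125-state
#' lookup.
#'
#' @param lookup Data frame with columns \code{state} and \code{value}
#'   covering all 3125 states, or \code{NULL}.
#' @param coefficients Named numeric vector of decrements with names like
#'   \code{"mo2"}, \code{"pd5"} (dimension code + level 2..5), or \code{NULL}.
#'   Exactly one of \code{lookup}/\code{coefficients} must be given.
#' @param name Label for the value set.
#' @return Object of class \code{eq5d_value_set} with elements \code{name},
#'   \code{values} (named vector over the 3125 states), \code{floor} and
#'   \code{anchor}.
#' @export
value_set <- function(lookup = NULL, coefficients = NULL, name = "value set") {
  if (is.null(lookup) == is.null(coefficients))
    stop("supply exactly one of `lookup` or `coefficients`", call. = FALSE)
  states <- all_health_states()
  if (!is.null(coefficients)) {
    expected <- as.vector(outer(eq5d_dimensions, 2:5, paste0))
    missing_terms <- setdiff(expected, names(coefficients))
    if (length(missing_terms))
      stop("coefficient file lacks term(s): ",
           paste(missing_terms, collapse = ", "), call. = FALSE)
    lv <- state_levels(states)
    dec <- rep(0, length(states))
    for (d in eq5d_dimensions) {
      cd <- c(0, unname(coefficients[paste0(d, 2:5)]))
      dec <- dec + cd[lv[, d]]
    }
    values <- stats::setNames(1 - dec, states)
  } else {
    lookup <- as.data.frame(lookup)
    if (!all(c("state", "value") %in% names(lookup)))
      stop("lookup needs columns `state` and `value`", call. = FALSE)
    lk <- stats::setNames(as.numeric(lookup$value),
                          as.character(lookup$state))
    missing_states <- setdiff(states, names(lk))
    if (length(missing_states))
      stop("value set does not resolve state(s): ",
           paste(utils::head(missing_states, 5), collapse = ", "),
           if (length(missing_states) > 5) ", ...", call. = FALSE)
    values <- lk[states]
  }
  vs <- structure(
    list(name = name, values = values,
         floor = min(values), anchor = unname(values[["11111"]])),
    class = "eq5d_value_set")
  validate_value_set(vs)
  vs
}

#' Validate a value set
#'
#' Checks that the full-health anchor is 1, that all indices lie in
#' \code{[floor, 1]}, and that the index is weakly monotone (worsening any
#' single dimension never increases the index). Violations of monotonicity
#' or anchoring in a supplied tariff raise a warning, not an error, so that
#' imperfect published files remain usable.
#'
#' @param vs An \code{eq5d_value_set}.
#' @return \code{vs}, invisibly.
#' @export
validate_value_set <- function(vs) {
  stopifnot(inherits(vs, "eq5d_value_set"))
  if (abs(vs$anchor - 1) > 1e-9)
    warning("value set anchor: index(\"11111\") = ", vs$anchor,
            " differs from 1.0", call. = FALSE)
  if (any(vs$values > 1 + 1e-9))
    warning("value set has indices above 1.0", call. = FALSE)
  # monotonicity: reshape onto the 5^5 grid and difference along each axis
  a <- array(vs$values[all_health_states()], dim = rep(5L, 5L))
  n_viol <- 0L
  for (d in 1:5) {
    dif <- apply(a, setdiff(1:5, d), diff)  # value(level+1) - value(level)
    n_viol <- n_viol + sum(dif > 1e-9)
  }
  if (n_viol > 0L)
    warning("value set violates weak monotonicity in ", n_viol,
            " level transition(s)", call. = FALSE)
  invisible(vs)
}

#' Score health states with a value set
#'
#' Pure lookup: deterministic, no side effects.
#'
#' @param state Character vector of 5-digit health-state codes.
#' @param vs An \code{eq5d_value_set}.
#' @return Numeric utility index per state.
#' @export
apply_value_set <- function(state, vs) {
  stopifnot(inherits(vs, "eq5d_value_set"))
  state_levels(state)  # validates the codes
  v <- unname(vs$values[as.character(state)])
  if (anyNA(v))
    stop("value set has no entry for state(s): ",
         paste(unique(state[is.na(v)]), collapse = ", "), call. = FALSE)
  v
}

#' Read a value set from a CSV file
#'
#' Accepts either a full lookup (columns \code{state,value}; 3125 rows) or an
#' additive coefficient file (columns \code{term,value} with terms
#' \code{mo2..ad5}).
#'
#' @param path Path to the CSV file.
#' @param name Optional label; defaults to the file name.
#' @return An \code{eq5d_value_set}.
#' @export
read_value_set <- function(path, name = basename(path)) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (all(c("state", "value") %in% names(df))) {
    value_set(lookup = df, name = name)
  } else if (all(c("term", "value") %in% names(df))) {
    value_set(coefficients = stats::setNames(df$value, df$term), name = name)
  } else {
    stop("value-set file must have columns state,value or term,value",
         call. = FALSE)
  }
}

#' @export
print.eq5d_value_set <- function(x, ...) {
  cat("EQ-5D-5L value set:", x$name, "\n")
  cat(sprintf("  anchor (11111): %.3f   floor (min): %.3f   states: %d\n",
              x$anchor, x$floor, length(x$values)))
  invisible(x)
}

#' Bundled synthetic example value set
#'
#' Loads the additive-coefficient value set shipped with the package. The
#' coefficients are synthetic (constructed for testing and examples, not a
#' published national tariff) but share the qualitative structure of
#' published EQ-5D-5L tariffs: anchor 1 at full health, weak monotonicity,
#' and a floor of -0.600 at state "55555".
#'
#' @return An \code{eq5d_value_set}.
#' @export
synthetic_value_set <- function() {
  read_value_set(
    system.file("extdata", "valueset_synthetic_coefficients.csv",
                package = "needlecea", mustWork = TRUE),
    name = "synthetic example tariff")
}
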