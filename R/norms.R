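#' @useDynLib collrep, .registration = TRUE
#' @importFrom Rcpp evalCpp
NULL

# Norm ids and the common-name aliases used in the indirect-reciprocity
# literature.
.norm_ids <- c(paste0("L", 1:8), "ALLC", "ALLD")

.norm_aliases <- c(
  "Consistent Standing" = "L2",
  "Simple Standing"     = "L3",
  "Stern Judging"       = "L6",
  "Staying"             = "L7",
  "Judging"             = "L8"
)

# The leading-eight tables differ only in three assessment cells and one
# action cell; everything else is shared.  Entries are stored per norm as the
# value of d(.|ra, rp, b) and b(ra, rp), 1 = good/cooperate, 0 = bad/defect.
#
# Variable cells (the triple (d(C|G,B), d(C|B,B), d(D|B,B)) runs through all
# eight binary combinations across L1..L8):
.l8_var <- data.frame(
  id        = paste0("L", 1:8),
  d_C_GB    = c(1, 0, 1, 1, 0, 0, 1, 0),
  d_C_BB    = c(1, 1, 1, 0, 1, 0, 0, 0),
  d_D_BB    = c(0, 0, 1, 1, 1, 1, 0, 0),
  action_BB = c(1, 1, 0, 0, 0, 0, 0, 0)
)

# key helpers: assessment entries are named "ra<G/B>|rp<G/B>|b<C/D>",
# action entries "ra<G/B>|rp<G/B>".
.rep_chr <- function(x) ifelse(x == 1L, "G", "B")
.act_chr <- function(x) ifelse(x == 1L, "C", "D")

.assess_key <- function(ra, rp, b) {
  paste0("ra", .rep_chr(ra), "|rp", .rep_chr(rp), "|b", .act_chr(b))
}
.action_key <- function(ra, rp) paste0("ra", .rep_chr(ra), "|rp", .rep_chr(rp))

# canonical ordering of the 8 assessment / 4 action contexts
.assess_contexts <- expand.grid(b = 1:0, rp = 1:0, ra = 1:0)[, c("ra", "rp", "b")]
.action_contexts <- expand.grid(rp = 1:0, ra = 1:0)[, c("ra", "rp")]

.build_table <- function(id) {
  if (id %in% c("ALLC", "ALLD")) {
    v <- if (id == "ALLC") 1L else 0L
    assessment <- rep(v, 8L)
    action <- rep(v, 4L)
  } else {
    row <- .l8_var[.l8_var$id == id, ]
    # shared leading-eight entries
    d <- function(ra, rp, b) {
      if (rp == 1L && b == 1L) return(1L)          # cooperation with good: good
      if (rp == 1L && b == 0L) return(0L)          # defection against good: bad
      if (ra == 1L && rp == 0L && b == 0L) return(1L)  # justified defection
      if (rp == 0L && b == 1L && ra == 1L) return(row$d_C_GB)
      if (ra == 0L && rp == 0L && b == 1L) return(row$d_C_BB)
      if (ra == 0L && rp == 0L && b == 0L) return(row$d_D_BB)
      stop("unreachable")
    }
    assessment <- mapply(d, .assess_contexts$ra, .assess_contexts$rp,
                         .assess_contexts$b)
    b <- function(ra, rp) {
      if (rp == 1L) return(1L)                     # cooperate with good groups
      if (ra == 1L && rp == 0L) return(0L)         # defect against bad groups
      row$action_BB
    }
    action <- mapply(b, .action_contexts$ra, .action_contexts$rp)
  }
  assessment <- as.integer(assessment)
  action <- as.integer(action)
  names(assessment) <- .assess_key(.assess_contexts$ra, .assess_contexts$rp,
                                   .assess_contexts$b)
  names(action) <- .action_key(.action_contexts$ra, .action_contexts$rp)
  structure(list(id = id, assessment = assessment, action = action),
            class = "strategy_table")
}

.table_cache <- local({
  tabs <- lapply(.norm_ids, .build_table)
  names(tabs) <- .norm_ids
  tabs
})

#' Retrieve a social-norm strategy table
#'
#' Returns the full assessment rule \eqn{d(r_a, r_p, b)} (8 entries) and
#' action rule \eqn{b(r_a, r_p)} (4 entries) for one of the leading-eight
#' norms `L1`..`L8` or the unconditional strategies `ALLC`/`ALLD`.
#' Reputations and actions are binary: 1 = good (G) / cooperate (C),
#' 0 = bad (B) / defect (D).  `ALLC` assessments are constantly good and its
#' actions constantly cooperative; `ALLD` is the mirror image.
#'
#' Common names from the literature are accepted as aliases:
#' `"Consistent Standing"` (L2), `"Simple Standing"` (L3),
#' `"Stern Judging"` (L6), `"Staying"` (L7), `"Judging"` (L8).
#'
#' @param id a norm identifier (`"L1"`..`"L8"`, `"ALLC"`, `"ALLD"`) or alias.
#' @return an object of class `strategy_table`: a list with elements `id`,
#'   `assessment` (named integer vector of length 8, names like
#'   `"raG|rpB|bC"`) and `action` (named integer vector of length 4, names
#'   like `"raB|rpB"`).
#' @examples
#' tab <- leading_eight_table("L6")            # Stern Judging
#' tab$assessment[["raB|rpB|bD"]]              # justified defection -> good
#' leading_eight_table("Staying")$id           # "L7"
#' @export
leading_eight_table <- function(id) {
  stopifnot(is.character(id), length(id) == 1L)
  if (id %in% names(.norm_aliases)) id <- .norm_aliases[[id]]
  if (!id %in% .norm_ids) {
    stop("unknown strategy id '", id, "'; valid ids: ",
         paste(c(.norm_ids, names(.norm_aliases)), collapse = ", "))
  }
  .table_cache[[id]]
}

#' Assess a donor's action
#'
#' Pure lookup in a norm's assessment rule: the new reputation an observer
#' assigns to a donor, given the donor's prior reputation in the observer's
#' eyes (`donor_rep`), the observer's collective reputation of the recipient
#' group (`group_rep`) and the action the observer perceived.
#'
#' @param table a `strategy_table`.
#' @param donor_rep,group_rep binary reputations (1 = good, 0 = bad).
#' @param observed binary action (1 = cooperate, 0 = defect).
#' @return binary reputation (integer 0/1).
#' @examples
#' assess(leading_eight_table("L7"), 1, 0, 1)  # good donor helps bad group: good
#' @export
assess <- function(table, donor_rep, group_rep, observed) {
  stopifnot(inherits(table, "strategy_table"))
  .check_binary(donor_rep, "donor_rep")
  .check_binary(group_rep, "group_rep")
  .check_binary(observed, "observed")
  table$assessment[[.assess_key(donor_rep, group_rep, observed)]]
}

#' Choose a donor's action
#'
#' Pure lookup in a norm's action rule: cooperate or defect given the donor's
#' self-reputation and the donor's collective reputation of the recipients.
#'
#' @inheritParams assess
#' @param self_rep the donor's own reputation in its own eyes (binary).
#' @return binary action (integer 0/1; 1 = cooperate).
#' @export
act <- function(table, self_rep, group_rep) {
  stopifnot(inherits(table, "strategy_table"))
  .check_binary(self_rep, "self_rep")
  .check_binary(group_rep, "group_rep")
  table$action[[.action_key(self_rep, group_rep)]]
}

.check_binary <- function(x, what) {
  if (length(x) != 1L || !x %in% c(0, 1))
    stop(what, " must be a single 0/1 value")
  invisible(TRUE)
}

#' @export
print.strategy_table <- function(x, ...) {
  cat("<strategy_table>", x$id, "\n")
  cat("assessment:\n")
  print(x$assessment)
  cat("action:\n")
  print(x$action)
  invisible(x)
}

#' Serialize strategy tables to/from JSON
#'
#' `strategy_to_json()` renders a table as a plain JSON dictionary
#' `{id, assessment, action}`; `strategy_from_json()` parses it back.
#' A versioned copy of all ten tables ships in
#' `system.file("extdata", "leading_eight.json", package = "collrep")`.
#'
#' @param table a `strategy_table`.
#' @param json a JSON string (or file path for `strategy_from_json`).
#' @return `strategy_to_json`: a JSON string; `strategy_from_json`: a
#'   `strategy_table`.
#' @export
strategy_to_json <- function(table) {
  stopifnot(inherits(table, "strategy_table"))
  jsonlite::toJSON(list(id = table$id,
                        assessment = as.list(table$assessment),
                        action = as.list(table$action)),
                   auto_unbox = TRUE, pretty = TRUE)
}

#' @rdname strategy_to_json
#' @export
strategy_from_json <- function(json) {
  obj <- jsonlite::fromJSON(json)
  tab <- structure(list(
    id = obj$id,
    assessment = vapply(obj$assessment, as.integer, integer(1)),
    action = vapply(obj$action, as.integer, integer(1))
  ), class = "strategy_table")
  .validate_table(tab)
  tab
}

.validate_table <- function(tab) {
  if (!setequal(names(tab$assessment),
                .assess_key(.assess_contexts$ra, .assess_contexts$rp,
                            .assess_contexts$b)) ||
      !setequal(names(tab$action),
                .action_key(.action_contexts$ra, .action_contexts$rp)))
    stop("incomplete strategy table for '", tab$id, "'")
  if (!all(c(tab$assessment, tab$action) %in% c(0L, 1L)))
    stop("non-binary entries in strategy table '", tab$id, "'")
  invisible(tab)
}

#' List the available strategy ids
#' @return character vector of the ten strategy ids.
#' @export
norm_ids <- function() .norm_ids

# ---- internal compiled representation used by the simulation engines ----
# assessment index (0-based): ra*4 + rp*2 + b; action index: ra*2 + rp
.compile_table <- function(tab) {
  a8 <- integer(8)
  for (ra in 0:1) for (rp in 0:1) for (b in 0:1)
    a8[ra * 4L + rp * 2L + b + 1L] <- tab$assessment[[.assess_key(ra, rp, b)]]
  a4 <- integer(4)
  for (ra in 0:1) for (rp in 0:1)
    a4[ra * 2L + rp + 1L] <- tab$action[[.action_key(ra, rp)]]
  list(assessment = a8, action = a4)
}
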