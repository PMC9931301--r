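# Who-saw-what audit log for the in-process federation simulator.
# Every cross-site message is recorded as (round, sender, receiver, type);
# the central privacy claim of hybrid mode is checkable as a predicate on
# this log: the aggregator never receives an unmasked local statistic.

#' Create an empty audit log
#'
#' @return An environment of class `fedtte_audit` accumulating message
#'   records; convert with [as.data.frame()].
#' @export
new_audit_log <- function() {
  e <- new.env(parent = emptyenv())
  e$records <- list()
  class(e) <- "fedtte_audit"
  e
}

audit_record <- function(audit, round, sender, receiver, type) {
  if (is.null(audit)) return(invisible(NULL))
  audit$records[[length(audit$records) + 1L]] <-
    list(round = as.integer(round), sender = sender,
         receiver = receiver, type = type)
  invisible(NULL)
}

#' @export
as.data.frame.fedtte_audit <- function(x, ...) {
  if (length(x$records) == 0)
    return(data.frame(round = integer(), sender = character(),
                      receiver = character(), type = character(),
                      stringsAsFactors = FALSE))
  do.call(rbind, lapply(x$records, function(r)
    data.frame(round = r$round, sender = r$sender, receiver = r$receiver,
               type = r$type, stringsAsFactors = FALSE)))
}

#' @export
print.fedtte_audit <- function(x, ...) {
  df <- as.data.frame(x)
  cat(sprintf("Federation audit log: %d messages\n", nrow(df)))
  if (nrow(df)) {
    tab <- table(sub(":.*$", "", df$type))
    for (nm in names(tab)) cat(sprintf("  %-20s %d\n", nm, tab[[nm]]))
  }
  invisible(x)
}

#' Check that the aggregator never saw an unmasked local statistic
#'
#' Scans an audit log for messages delivered to the aggregator whose type
#' marks them as raw (unmasked) local statistics. In hybrid mode this must
#' return `TRUE`; in plain federated mode local aggregates are sent in the
#' clear by design and it returns `FALSE`.
#'
#' @param audit A `fedtte_audit` log.
#' @return Logical.
#' @export
aggregator_blind <- function(audit) {
  df <- as.data.frame(audit)
  !any(df$receiver == "aggregator" & startsWith(df$type, "local_"))
}
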