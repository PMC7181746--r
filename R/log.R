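# Audit-trail logging.  Every filtering or inference decision is narrated so
# a per-patient run can be reviewed rule by rule.  Messages are collected
# into an in-memory buffer (retrievable by the caller) and echoed through
# message() when options(metroutes.verbose = TRUE).

mr_new_log <- function() {
  env <- new.env(parent = emptyenv())
  env$lines <- character()
  env
}

mr_log <- function(log, fmt, ...) {
  if (is.null(log)) return(invisible(NULL))
  line <- sprintf(fmt, ...)
  log$lines <- c(log$lines, line)
  if (isTRUE(getOption("metroutes.verbose", FALSE))) message("[metroutes] ", line)
  invisible(NULL)
}

mr_log_lines <- function(log) if (is.null(log)) character() else log$lines
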