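#' Recording-quality check
#'
#' Flags recordings whose leak current exceeds `leak_max` or whose seal
#' resistance falls below `seal_min`.  Both criteria are strict
#' inequalities, so boundary values (leak exactly 25 pA, seal exactly
#' 1 GOhm) pass.  Metadata that was never measured (`NA`) does not fail a
#' cell; it is reported as `"not_measured"`.
#'
#' @param rec an `ephys_recording` carrying `leak_pA` / `seal_Gohm`.
#' @param leak_max maximum acceptable leak current, pA (default 25).
#' @param seal_min minimum acceptable seal resistance, GOhm (default 1).
#' @return A list of class `qc_report` with fields `leak_current`,
#'   `seal_resistance`, `pass`, `reasons`.
#' @export
qc_recording <- function(rec, leak_max = 25, seal_min = 1) {
  stopifnot(inherits(rec, "ephys_recording"))
  leak <- rec$leak_pA
  seal <- rec$seal_Gohm
  if (!is.na(seal) && seal < 0)
    stop("qc_recording: negative seal resistance (data error)")
  reasons <- character(0)
  if (is.na(leak) || is.na(seal)) reasons <- c(reasons, "not_measured")
  if (!is.na(leak) && leak > leak_max) reasons <- c(reasons, "leak")
  if (!is.na(seal) && seal < seal_min) reasons <- c(reasons, "seal")
  structure(list(cell_id = rec$cell_id,
                 leak_current = leak, seal_resistance = seal,
                 pass = !any(reasons %in% c("leak", "seal")),
                 reasons = reasons),
            class = "qc_report")
}

#' @export
print.qc_report <- function(x, ...) {
  cat(sprintf("<qc_report> cell %s: %s (leak %s pA, seal %s GOhm)%s\n",
              x$cell_id, if (x$pass) "PASS" else "FAIL",
              format(x$leak_current), format(x$seal_resistance),
              if (length(x$reasons)) paste0(" [", paste(x$reasons, collapse = ","), "]")
              else ""))
  invisible(x)
}
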