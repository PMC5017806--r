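#' Validate a tidy assay table
#'
#' The canonical exchange schema across the package: long format with
#' columns `time_d` (days, >= 0), `replicate`, `analyte` (one of `Fe2`,
#' `FeTot`, `NO3`, `NO2`) and `conc_mM` (>= 0). No duplicate
#' (time, replicate, analyte) keys; wherever a tube reports both, FeTot must
#' be at least Fe2. Errors name the offending row.
#'
#' @param table data frame to check.
#' @return the table, invisibly row-canonicalized (sorted by time,
#'   replicate, analyte).
#' @export
validate_assay <- function(table) {
  if (!is.data.frame(table)) stop("assay table must be a data frame")
  required <- c("time_d", "replicate", "analyte", "conc_mM")
  miss <- setdiff(required, names(table))
  if (length(miss)) stop("assay table missing column(s): ", paste(miss, collapse = ", "))
  table <- as.data.frame(table)[required]
  table$replicate <- as.character(table$replicate)
  table$analyte <- as.character(table$analyte)

  analytes <- c("Fe2", "FeTot", "NO3", "NO2")
  aliases <- c("Fe(II)" = "Fe2", "FeII" = "Fe2", "Fe2+" = "Fe2",
               "ferrous" = "Fe2", "Fe(tot)" = "FeTot", "FeT" = "FeTot",
               "Fetot" = "FeTot", "totalFe" = "FeTot",
               "NO3-" = "NO3", "nitrate" = "NO3",
               "NO2-" = "NO2", "nitrite" = "NO2")
  bad <- which(!(table$analyte %in% analytes))
  if (length(bad)) {
    i <- bad[1]
    hint <- aliases[table$analyte[i]]
    stop("row ", i, ": unknown analyte '", table$analyte[i], "'",
         if (!is.na(hint)) paste0("; did you mean '", hint, "'?") else
           paste0("; expected one of ", paste(analytes, collapse = ", ")))
  }
  if (anyNA(table$time_d) || anyNA(table$conc_mM)) {
    i <- which(is.na(table$time_d) | is.na(table$conc_mM))[1]
    stop("row ", i, ": missing time or concentration")
  }
  if (any(table$time_d < 0)) {
    stop("row ", which(table$time_d < 0)[1], ": negative time")
  }
  if (any(table$conc_mM < 0)) {
    stop("row ", which(table$conc_mM < 0)[1], ": negative concentration")
  }
  key <- paste(table$time_d, table$replicate, table$analyte, sep = "\r")
  if (anyDuplicated(key)) {
    stop("row ", which(duplicated(key))[1], ": duplicate (time, replicate, analyte) key")
  }
  # FeTot >= Fe2 wherever both present at a key
  fe2 <- table[table$analyte == "Fe2", ]
  tot <- table[table$analyte == "FeTot", ]
  if (nrow(fe2) && nrow(tot)) {
    k2 <- paste(fe2$time_d, fe2$replicate, sep = "\r")
    kt <- paste(tot$time_d, tot$replicate, sep = "\r")
    m <- match(k2, kt)
    hit <- which(!is.na(m) & fe2$conc_mM > tot$conc_mM[m] + 1e-9)
    if (length(hit)) {
      row_in_table <- which(table$analyte == "Fe2")[hit[1]]
      stop("row ", row_in_table, ": FeTot < Fe2 at time ", fe2$time_d[hit[1]],
           " d, replicate ", fe2$replicate[hit[1]])
    }
  }
  out <- table[order(table$time_d, table$replicate, table$analyte), , drop = FALSE]
  rownames(out) <- NULL
  invisible(out)
}

#' Read a tidy assay CSV
#'
#' Comma-separated, UTF-8, header mandatory, long format; see
#' [validate_assay()] for the schema.
#'
#' @param path CSV file path.
#' @return validated assay data frame.
#' @export
read_assay <- function(path) {
  if (!file.exists(path)) stop("no such assay file: ", path)
  tab <- utils::read.csv(path, stringsAsFactors = FALSE, fileEncoding = "UTF-8")
  out <- validate_assay(tab)
  out
}

#' Write a tidy assay CSV
#'
#' @param table assay data frame (validated before writing).
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_assay <- function(table, path) {
  table <- validate_assay(table)
  utils::write.csv(table, path, row.names = FALSE, quote = FALSE,
                   fileEncoding = "UTF-8")
  invisible(path)
}

#' Derive Fe(III) from total and ferrous iron
#'
#' Fe(III) is never stored in the assay schema: it is measured as the
#' difference between total iron (after hydroxylamine reduction) and
#' ferrous iron, and is derived the same way here.
#'
#' @param table assay data frame containing `Fe2` and `FeTot` rows.
#' @return data frame (`time_d`, `replicate`, `fe3_mM`).
#' @export
fe3_from_assay <- function(table) {
  table <- validate_assay(table)
  fe2 <- table[table$analyte == "Fe2", ]
  tot <- table[table$analyte == "FeTot", ]
  if (!nrow(fe2) || !nrow(tot)) stop("need both Fe2 and FeTot rows to derive Fe(III)")
  k2 <- paste(fe2$time_d, fe2$replicate, sep = "\r")
  kt <- paste(tot$time_d, tot$replicate, sep = "\r")
  m <- match(k2, kt)
  keep <- !is.na(m)
  data.frame(
    time_d = fe2$time_d[keep],
    replicate = fe2$replicate[keep],
    fe3_mM = tot$conc_mM[m[keep]] - fe2$conc_mM[keep]
  )
}
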