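#' Promoter library presence and integration outcomes
#'
#' The bundled table records, for the 13-promoter transcriptional-reporter
#' library injected into the tested array line, whether each promoter was
#' detected in the array (`array`) and whether it was confirmed as a
#' genomic integrant by sequencing (`integrated`), with promoter sizes in
#' bp. It is the package's worked example of presence/integration
#' filtering: integration requires presence in the array, and a promoter
#' can be present yet never recovered among integrants.
#'
#' @param path Path to a presence TSV; defaults to the bundled table.
#' @return `read_promoter_table`: a tibble with columns `promoter`,
#'   `promoter_size_bp`, `array`, `integrated` (`"Y"`/`"N"`).
#' @examples
#' tab <- read_promoter_table()
#' promoter_presence_summary(tab)
#' @export
read_promoter_table <- function(path = system.file(
  "extdata", "promoter_array_presence.tsv", package = "tardisbarseq")) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  stopifnot(all(c("promoter", "array", "integrated") %in% names(df)))
  tibble::as_tibble(df)
}

#' @rdname read_promoter_table
#' @param table A promoter table from [read_promoter_table()].
#' @return `promoter_presence_summary`: a list with `n_injected`,
#'   `n_in_array`, `n_integrated`, and `n_in_array_not_integrated`.
#' @export
promoter_presence_summary <- function(table = read_promoter_table()) {
  in_array <- table$array == "Y"
  integrated <- table$integrated == "Y"
  if (any(integrated & !in_array)) {
    stop("inconsistent table: integrated promoter absent from array",
         call. = FALSE)
  }
  list(
    n_injected = nrow(table),
    n_in_array = sum(in_array),
    n_integrated = sum(integrated),
    n_in_array_not_integrated = sum(in_array & !integrated)
  )
}
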