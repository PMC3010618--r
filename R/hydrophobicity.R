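#' Hydrophobicity scales
#'
#' A hydrophobicity scale maps each of the 20 standard one-letter amino-acid
#' codes to a real number. The built-in default is the Kyte-Doolittle
#' hydropathy index; any complete custom scale can be supplied instead, so
#' the mapping is always explicit and reproducible.
#'
#' @param name `"kyte-doolittle"` (the only built-in), or a named numeric
#'   vector covering exactly the 20 standard codes, or a path to a 2-column
#'   text file (code, value).
#' @return A `HydrophobicityScale`: list with `name` and `values` (named
#'   numeric vector over the 20 codes).
#' @export
hydrophobicity_scale <- function(name = "kyte-doolittle") {
  if (is.character(name) && length(name) == 1 && file.exists(name)) {
    tab <- utils::read.table(name, header = FALSE, comment.char = "#",
                             stringsAsFactors = FALSE)
    if (ncol(tab) < 2) stop("scale file must have 2 columns: code, value")
    vals <- stats::setNames(as.numeric(tab[[2]]), toupper(tab[[1]]))
    return(new_scale(basename(name), vals))
  }
  if (is.numeric(name)) return(new_scale("custom", name))
  name <- match.arg(tolower(name), "kyte-doolittle")
  new_scale("kyte-doolittle", KYTE_DOOLITTLE)
}

KYTE_DOOLITTLE <- c(
  A =  1.8, R = -4.5, N = -3.5, D = -3.5, C =  2.5,
  Q = -3.5, E = -3.5, G = -0.4, H = -3.2, I =  4.5,
  L =  3.8, K = -3.9, M =  1.9, F =  2.8, P = -1.6,
  S = -0.8, T = -0.7, W = -0.9, Y = -1.3, V =  4.2)

AA_CODES <- names(KYTE_DOOLITTLE)

new_scale <- function(name, values) {
  values <- values[order(names(values))]
  if (!setequal(names(values), AA_CODES) || length(values) != 20)
    stop("HydrophobicityScale: exactly the 20 standard one-letter codes ",
         "must be present; missing: ",
         paste(setdiff(AA_CODES, names(values)), collapse = ", "))
  if (anyNA(values)) stop("HydrophobicityScale: NA value in scale")
  structure(list(name = name, values = values),
            class = "HydrophobicityScale")
}

#' Build a hydrophobicity signal from an amino-acid sequence
#'
#' Assigns a hydrophobicity value to each amino acid in sequence order,
#' producing a 1D signal of the same length as the sequence. Positions with
#' the ambiguity code `'X'` become gap positions in the signal.
#'
#' @param seq Amino-acid string over the 20 one-letter codes plus `'X'`
#'   (case-insensitive), non-empty.
#' @param scale A `HydrophobicityScale` (default Kyte-Doolittle).
#' @param protein_id Identifier for the resulting signal.
#' @return A `FlexibilitySignal` of kind `"HYDROPHOBICITY"`.
#' @export
hydrophobicity_signal <- function(seq, scale = hydrophobicity_scale(),
                                  protein_id = "seq") {
  stopifnot(inherits(scale, "HydrophobicityScale"))
  seq <- toupper(gsub("[[:space:]]", "", as.character(seq)[1]))
  if (!nzchar(seq)) stop("hydrophobicity_signal: empty sequence")
  chars <- strsplit(seq, "")[[1]]
  bad <- !(chars %in% c(AA_CODES, "X"))
  if (any(bad))
    stop("hydrophobicity_signal: unknown amino-acid code '",
         chars[which(bad)[1]], "' at position ", which(bad)[1])
  gaps <- chars == "X"
  vals <- rep(0, length(chars))
  vals[!gaps] <- unname(scale$values[chars[!gaps]])
  flexibility_signal(protein_id, vals, kind = "HYDROPHOBICITY",
                     gap_mask = gaps)
}
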