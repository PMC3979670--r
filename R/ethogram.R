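#' Behavior categories
#'
#' The four mutually exclusive category labels an ethogram behavior can carry.
#' @keywords internal
BEHAVIOR_CATEGORIES <- c("non_interactive", "interactive_nonaggressive",
                         "low_intensity_aggression", "high_intensity_aggression")

# Raw scoring names of the six low-intensity aggressive acts that are
# collapsed into the single analysis code "Lo".
LOW_INTENSITY_RAW <- c("chop", "uppercut", "back kick", "head butt",
                       "fencing", "boxing")

#' Construct an ethogram
#'
#' An ethogram is the closed registry of discrete, mutually exclusive behavior
#' codes used to score an encounter, each carrying a human-readable name and
#' one of four category labels: `non_interactive`,
#' `interactive_nonaggressive`, `low_intensity_aggression`, or
#' `high_intensity_aggression`.
#'
#' @param code character vector of short, case-sensitive behavior tokens
#'   (e.g. `"W"`, `"Sta"`, `"Wr"`).
#' @param name character vector of behavior names.
#' @param category character vector of category labels, one of
#'   `r paste0('\x60', BEHAVIOR_CATEGORIES, '\x60', collapse = ", ")`.
#' @return An object of class `ethogram`: a data frame with columns `code`,
#'   `name`, `category`, in the given order, with attribute `k` (the number
#'   of behaviors, i.e. the transition-matrix dimension).
#' @examples
#' ethogram("W", "Walking", "non_interactive")
#' @export
ethogram <- function(code, name, category) {
  code <- as.character(code); name <- as.character(name)
  category <- as.character(category)
  if (length(code) == 0L) stop("an ethogram needs at least one behavior")
  if (any(!nzchar(code)) || anyNA(code)) stop("behavior codes must be non-empty")
  dup <- unique(code[duplicated(code)])
  if (length(dup)) {
    stop("duplicate behavior code(s) in ethogram: ", paste(dup, collapse = ", "))
  }
  bad <- setdiff(unique(category), BEHAVIOR_CATEGORIES)
  if (length(bad)) {
    stop("unknown behavior category token(s): ", paste(bad, collapse = ", "),
         " (expected one of ", paste(BEHAVIOR_CATEGORIES, collapse = ", "), ")")
  }
  stopifnot(length(name) == length(code), length(category) == length(code))
  out <- data.frame(code = code, name = name, category = category,
                    stringsAsFactors = FALSE)
  class(out) <- c("ethogram", "data.frame")
  attr(out, "k") <- nrow(out)
  out
}

#' @export
print.ethogram <- function(x, ...) {
  cat("<ethogram> ", nrow(x), " behaviors\n", sep = "")
  print.data.frame(x, row.names = FALSE)
  invisible(x)
}

#' Load an ethogram definition file
#'
#' Reads a 3-column CSV (`code,name,category`, UTF-8) and validates it.
#' Behavior order is preserved as given in the file.
#'
#' @param path path to the definition CSV.
#' @return An [ethogram].
#' @export
load_ethogram <- function(path) {
  if (!file.exists(path)) stop("ethogram file not found: ", path)
  df <- utils::read.csv(path, stringsAsFactors = FALSE, encoding = "UTF-8")
  need <- c("code", "name", "category")
  if (!all(need %in% names(df))) {
    stop("ethogram file must have header 'code,name,category'")
  }
  ethogram(df$code, df$name, df$category)
}

#' The default paired-male flesh-fly ethogram
#'
#' The packaged 16-behavior repertoire used for the dyadic encounter analyses
#' (codes U, B, G, I, J, T, H, Wr, Av, W, Ap, Lo, L, R, Sti, Sta), with the
#' six low-intensity aggressive acts already collapsed into the single code
#' `Lo`.
#'
#' @return An [ethogram] with k = 16.
#' @examples
#' eth <- default_ethogram()
#' attr(eth, "k")
#' @export
default_ethogram <- function() {
  load_ethogram(system.file("extdata", "ethogram_paired_male.csv",
                            package = "ethoseq", mustWork = TRUE))
}

#' Collapse raw low-intensity aggression codes
#'
#' The six low-intensity aggressive acts (chop, uppercut, back kick,
#' head butt, fencing, boxing) occur too rarely to analyze individually and
#' are scored as the single analysis code `"Lo"`. Any other code passes
#' through unchanged, so the function is idempotent.
#'
#' @param raw_code character vector of raw or analysis behavior codes.
#' @return character vector with low-intensity raw names replaced by `"Lo"`.
#' @examples
#' collapse_low_intensity(c("boxing", "Wr", "chop"))
#' @export
collapse_low_intensity <- function(raw_code) {
  raw <- tolower(gsub("[_-]", " ", as.character(raw_code)))
  ifelse(raw %in% LOW_INTENSITY_RAW, "Lo", as.character(raw_code))
}

#' Category of a behavior code
#'
#' @param eth an [ethogram].
#' @param code a single behavior code present in `eth`.
#' @return The category label of `code`.
#' @examples
#' category_of(default_ethogram(), "I")
#' @export
category_of <- function(eth, code) {
  stopifnot(inherits(eth, "ethogram"), length(code) == 1L)
  i <- match(code, eth$code)
  if (is.na(i)) stop("unknown behavior code: ", code)
  eth$category[i]
}

#' High-intensity aggressive behavior codes of an ethogram
#'
#' For the default paired-male ethogram this is \{L, H, Wr, I\}: the
#' full-body-contact agonistic behaviors.
#'
#' @param eth an [ethogram].
#' @return Character vector of codes with category `high_intensity_aggression`.
#' @export
high_intensity_codes <- function(eth) {
  stopifnot(inherits(eth, "ethogram"))
  eth$code[eth$category == "high_intensity_aggression"]
}
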