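#' Element panels
#'
#' An element panel is the ordered set of element symbols quantified in one
#' screening campaign. Two presets are provided: the 14-element panel used for
#' the deletion (knockout) collections and the 17-element panel used for the
#' over-expression collection, which additionally carries As, Cl and Se.
#'
#' @param elements Character vector of element symbols.
#' @return An object of class `element_panel` (a character vector).
#' @examples
#' element_panel(c("Ca", "Fe", "Zn"))
#' panel_ko()
#' @export
element_panel <- function(elements) {
  elements <- as.character(elements)
  if (length(elements) == 0L) stop("element panel must be non-empty")
  if (anyDuplicated(elements)) {
    stop("element panel has duplicated symbols: ",
         paste(unique(elements[duplicated(elements)]), collapse = ", "))
  }
  structure(elements, class = "element_panel")
}

#' @rdname element_panel
#' @export
panel_ko <- function() {
  element_panel(c("Ca", "Cd", "Co", "Cu", "Fe", "K", "Mg",
                  "Mn", "Mo", "Na", "Ni", "P", "S", "Zn"))
}

#' @rdname element_panel
#' @export
panel_oe <- function() {
  element_panel(c("As", "Ca", "Cd", "Cl", "Co", "Cu", "Fe", "K", "Mg",
                  "Mn", "Mo", "Na", "Ni", "P", "S", "Se", "Zn"))
}

#' Size of the significance-pattern space
#'
#' Each gene's significance pattern assigns one of three states (significant
#' decrease, no change, significant increase) to every element, so a panel of
#' E elements admits 3^E distinct patterns.
#'
#' @param n_elements Number of elements in the panel (or an `element_panel`).
#' @return The number of possible sign patterns, `3^E`, as a double.
#' @examples
#' pattern_space_size(14)  # 4782969
#' @export
pattern_space_size <- function(n_elements) {
  if (inherits(n_elements, "element_panel")) n_elements <- length(n_elements)
  n_elements <- as.integer(n_elements)
  stopifnot(length(n_elements) == 1L, !is.na(n_elements), n_elements >= 1L)
  3^n_elements
}
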