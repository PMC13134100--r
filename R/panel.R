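#' The 20-item symptom panel
#'
#' The instrument layout the whole package assumes: nine depression items
#' (PHQ-9, each scored 0-3), seven generalised-anxiety items (GAD-7, each
#' scored 0-3), and four work/social functioning items (WSAS items 2-5, each
#' scored 0-8; the first WSAS item, ability to work, is routinely recorded
#' as not applicable for people out of employment and is excluded).
#'
#' @return An object of class \code{"symptom_panel"}: a data frame with one
#'   row per item and columns \code{item} (unique name), \code{instrument}
#'   (\code{"depression"}, \code{"anxiety"} or \code{"functioning"}),
#'   \code{index} (item number within its instrument), \code{min} and
#'   \code{max} (admissible score range).
#' @examples
#' panel <- symptom_panel()
#' nrow(panel)        # 20
#' table(panel$instrument)
#' @export
symptom_panel <- function() {
  panel <- rbind(
    data.frame(item = paste0("phq", 1:9), instrument = "depression",
               index = 1:9, min = 0, max = 3, stringsAsFactors = FALSE),
    data.frame(item = paste0("gad", 1:7), instrument = "anxiety",
               index = 1:7, min = 0, max = 3, stringsAsFactors = FALSE),
    data.frame(item = paste0("wsas", 2:5), instrument = "functioning",
               index = 2:5, min = 0, max = 8, stringsAsFactors = FALSE)
  )
  class(panel) <- c("symptom_panel", "data.frame")
  panel
}

#' @export
print.symptom_panel <- function(x, ...) {
  cat("Symptom panel:", nrow(x), "items\n")
  for (ins in unique(x$instrument)) {
    sub <- x[x$instrument == ins, ]
    cat(sprintf("  %-12s %2d items (%s), scored %d-%d\n", ins, nrow(sub),
                paste(range(sub$item), collapse = " .. "),
                sub$min[1], sub$max[1]))
  }
  invisible(x)
}

panel_items <- function(panel = symptom_panel()) panel$item

stopifnot_panel <- function(panel) {
  if (!inherits(panel, "symptom_panel")) stop("not a symptom_panel")
  if (nrow(panel) != 20L) stop("panel must have exactly 20 items")
  if (anyDuplicated(panel$item)) stop("panel item names must be unique")
  counts <- table(panel$instrument)
  if (counts[["depression"]] != 9L || counts[["anxiety"]] != 7L ||
      counts[["functioning"]] != 4L)
    stop("panel must have 9 depression, 7 anxiety and 4 functioning items")
  invisible(panel)
}
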