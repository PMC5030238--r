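#' Bundled example sentences with hand-built parses
#'
#' A small set of connectivity sentences from the neuroanatomy literature,
#' shipped with hand-transcribed constituency trees (\code{.ptb}) and typed
#' dependency triples (\code{.deps}) so that the argument-identification
#' rules can be exercised without running a parser. Names:
#' \describe{
#'   \item{scn_pa}{"The suprachiasmatic nucleus is well known to project
#'     densely to Pa in rats." -- first-NP-after and subject-group rule.}
#'   \item{parabrachial}{dependency triples only: subject-group rule with
#'     the keyword as governor.}
#'   \item{tracer_injection}{"An anterograde tracer injection into the
#'     dorsal midline thalamus revealed strong projections to ..." --
#'     dobj/nsubj special case.}
#'   \item{orexin_vmod}{dependency triples only: vmod rule.}
#'   \item{apvt_passive}{passive voice: "the aPVT was strongly innervated by
#'     the ventral subiculum".}
#'   \item{pvt_orexin}{"The paraventricular thalamus (PVT) ... receives
#'     dense innervations from lateral hypothalamic orexin neurons".}
#'   \item{pa_pt_dual}{dual-slot "projections from Pa, Pt, and other midline
#'     nuclei to the amygdala".}
#'   \item{pvt_innervate}{"... stress activates PVT neurons that innervate
#'     the PFC, NAS and AMG."}
#' }
#'
#' @param name example name; NULL lists available names.
#' @return for a single name, a list with \code{sentence} (an
#'   \code{nc_sentence} or NULL), \code{tree} (an \code{nc_ctree} or NULL)
#'   and \code{edges} (dependency data.frame or NULL); with \code{name =
#'   NULL}, the character vector of names.
#' @export
worked_example <- function(name = NULL) {
  dir <- system.file("extdata", "worked_examples", package = "neuroconn",
                     mustWork = TRUE)
  stems <- sort(unique(tools::file_path_sans_ext(list.files(dir))))
  if (is.null(name)) return(stems)
  if (!name %in% stems) {
    stop("unknown example '", name, "'; available: ",
         paste(stems, collapse = ", "))
  }
  path <- function(ext) file.path(dir, paste0(name, ext))
  sentence <- if (file.exists(path(".txt"))) {
    nc_sentence(paste0("we.", name), 0L,
                trimws(paste(readLines(path(".txt"), encoding = "UTF-8",
                                       warn = FALSE), collapse = " ")))
  } else NULL
  tree <- if (file.exists(path(".ptb"))) read_bracketed_tree(path(".ptb"))
          else NULL
  edges <- if (file.exists(path(".deps"))) {
    read_dependency_triples(path(".deps"))
  } else NULL
  list(sentence = sentence, tree = tree, edges = edges)
}
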