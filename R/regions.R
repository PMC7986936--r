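#' Region and latent-state atlas
#'
#' The analysis works on 55 regional volumes driven by 28 latent atrophy
#' states: 25 bilateral cortical region pairs share one state per pair
#' (bilateral symmetry of disease progression), the caudate and putamen are
#' each modelled as a single bilateral state observed in both hemispheres,
#' and global white matter is a single state with a single observed column.
#'
#' @return A data.frame with one row per observed region column (55 rows):
#'   `region` (column name used in visit tables), `state` (integer 1..28),
#'   `state_name`, `hemisphere` (`"L"`, `"R"` or `"bilateral"`), and `lobe`.
#' @examples
#' tab <- hd_region_table()
#' nrow(tab)                     # 55 observed columns
#' length(unique(tab$state))     # 28 latent states
#' @export
hd_region_table <- function() {
  .hd_region_table
}

#' Names of the 28 latent atrophy states
#'
#' @return Character vector of length 28, in state order.
#' @export
hd_state_names <- function() {
  tab <- .hd_region_table
  tab$state_name[!duplicated(tab$state)]
}

# cortical states grouped by lobe; 25 pairs + caudate + putamen + white matter
.hd_cortical <- list(
  frontal   = c("precentral", "superior_frontal", "middle_frontal",
                "inferior_frontal", "orbital_gyrus", "supplementary_motor"),
  limbic    = c("cingulate", "parahippocampal", "entorhinal"),
  temporal  = c("superior_temporal", "middle_temporal", "inferior_temporal",
                "temporal_pole", "planum_temporale", "fusiform"),
  parietal  = c("postcentral", "superior_parietal", "supramarginal",
                "angular", "precuneus"),
  occipital = c("calcarine", "cuneus", "lingual", "middle_occipital",
                "occipital_pole")
)

.build_region_table <- function() {
  cort <- data.frame(
    state_name = unlist(.hd_cortical, use.names = FALSE),
    lobe = rep(names(.hd_cortical), lengths(.hd_cortical)),
    stringsAsFactors = FALSE
  )
  rows <- do.call(rbind, lapply(seq_len(nrow(cort)), function(i) {
    data.frame(
      region = paste0(cort$state_name[i], c("_L", "_R")),
      state_name = cort$state_name[i],
      hemisphere = c("L", "R"),
      lobe = cort$lobe[i],
      stringsAsFactors = FALSE
    )
  }))
  sub <- data.frame(
    region = c("caudate_L", "caudate_R", "putamen_L", "putamen_R",
               "white_matter"),
    state_name = c("caudate", "caudate", "putamen", "putamen",
                   "white_matter"),
    hemisphere = c("L", "R", "L", "R", "bilateral"),
    lobe = c("subcortical", "subcortical", "subcortical", "subcortical",
             "white_matter"),
    stringsAsFactors = FALSE
  )
  tab <- rbind(rows, sub)
  states <- unique(tab$state_name)
  tab$state <- match(tab$state_name, states)
  tab[, c("region", "state", "state_name", "hemisphere", "lobe")]
}

.hd_region_table <- .build_region_table()

# lobe of each state, in state order (internal)
.state_lobes <- function() {
  tab <- .hd_region_table
  tab$lobe[!duplicated(tab$state)]
}
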