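#' Tetrapod presence/absence fixture for the exon-skipping character
#'
#' A rooted 20-tip tree over the tetrapod species assayed for skipping of the
#' D2 receptor cassette exon, with presence/absence of the short (skipping)
#' isoform at each tip: present in ranid frogs (Lca, Lpi), squamates (Aca,
#' Pvi), most birds (Apl, Gga, Tgu, Fal, Pmaj) and placental/marsupial
#' mammals sampled (Clu, Mmu, Hsa); absent in the newt (Nvi), tropical frogs
#' (Xtr, Xla), turtles (Cpi, Psi), ostrich (Sca), platypus (Oan) and koala
#' (Pci). On this tree the skipping character is most parsimoniously
#' explained by four independent gains (and no losses), versus one ancestral
#' gain plus six losses.
#'
#' @return List with `tree` ([ape::phylo]) and `tip_states` (named character
#'   vector).
#' @export
d2s_presence_fixture <- function() {
  newick <- paste0(
    "((Nvi,((Xtr,Xla),(Lca,Lpi))),((Oan,(Pci,(Clu,(Mmu,Hsa)))),",
    "((Aca,Pvi),((Cpi,Psi),(Sca,(Apl,(Gga,(Tgu,(Fal,Pmaj)))))))));")
  tree <- ape::read.tree(text = newick)
  present <- c("Lca", "Lpi", "Aca", "Pvi", "Apl", "Gga", "Tgu", "Fal",
               "Pmaj", "Clu", "Mmu", "Hsa")
  absent <- c("Nvi", "Xtr", "Xla", "Cpi", "Psi", "Sca", "Oan", "Pci")
  states <- setNames(c(rep("present", length(present)),
                       rep("absent", length(absent))),
                     c(present, absent))
  list(tree = tree, tip_states = states[tree$tip.label])
}

#' 29-species status table for the end-to-end scenario
#'
#' One row per species assayed for cassette-exon skipping in brain RNA-Seq:
#' 20 tetrapods (12 of which express both the inclusion and the skipping
#' isoform) plus a lamprey, a chimaeroid shark, a gar and six teleosts, none
#' of which express the skipping isoform in the CNS. Sequencing-depth tiers
#' are assigned cyclically and independently of presence, matching the
#' observation that detection of the skipping isoform is unrelated to depth.
#'
#' @return Tibble: `species_id`, `s_present` (logical), `depth_tier`
#'   (`low`/`mid`/`high`).
#' @export
species_status_fixture <- function() {
  fixture <- d2s_presence_fixture()
  tet <- tibble(species_id = names(fixture$tip_states),
                s_present = unname(fixture$tip_states == "present"))
  fish <- tibble(species_id = c("Pma", "Cmi", "Loc", "Dre", "Ame", "Cau",
                                "Pre", "Ssa", "Cse"),
                 s_present = FALSE)
  out <- bind_rows(tet, fish)
  out$depth_tier <- rep(c("low", "mid", "high"), length.out = nrow(out))
  out
}
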