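# Fixed packaged template sequences for the synthetic-proteome generator and
# the internal profile scanner.
#
# ALPHA_TEMPLATE (300 aa) models a Class I terpene-synthase alpha domain:
# DDxxD at 100-104, the NSE motif (N/D)Dxx(S/T/G)xxx(E/D) at 240-248
# (spacing 140, inside the Class I plausibility window), the bacterial-type
# key Ile at 216 and the plant-type PIx context at 219-221 (Ile 220, one
# helical turn after 216).
#
# GB_TEMPLATE (500 aa) models a Class II gamma-beta didomain: the catalytic
# dyad contexts LHS (His 187) and PNV (Asn 253) in the first (gamma) half and
# the DxDD catalytic acid motif at 300-303 in the second (beta) half.
#
# SHC_TEMPLATE (500 aa) is a squalene-hopene-cyclase-like decoy: an
# independent random basis sharing only the DxDD motif (300-303).
#
# All three were rejection-sampled so that no built-in motif matches anywhere
# except the planted sites (in both the canonical and aberrant alpha
# variants); planted sites are mutation-locked by the generator.

ALPHA_TEMPLATE <- paste0(
  "WEVYPHHLHNWMARVAREADWLSPRFPSGTVAFDDMSNVWGITRQKFPHEFCANINQFYV",
  "EVEHSFKDSEHGMCFFTHFPTFFTVLAMWSLMSFSQSCGDDTFDQVYYQTNNVQLGEDLA",
  "RFLQGTKEFPYFIHVLTMPVKEKHIHVFPRESITDDKNINLGFAYVPFLICMAYVDSTRH",
  "DWAELCQQSMRKYEWNTDGLWPRYIDDMLATVYLEIQPPILNRWHFICGGLAELTVYYVN",
  "DLISVVAEQVWFAAFHQKCTEYYPHISTHMWIDNCDYCKDMIWLKVPYVVITFGWNGSCH")

GB_TEMPLATE <- paste0(
  "NNQIYQMMWQTQIPGSLGEIMTPYGEPVLPRCCMKKGQDGLRWHIIGSEHRSENILYLSE",
  "CTCMLFWHWYPDPVTWKGYYVWCAVGSKLRMAWAIQKIWNVFWYECHKPDNDWGSPPWGT",
  "EGLGTQQSWMSASGHQEKKDSCKGIPYTLKATYVHTHQPDMHEHVYDLCYAAIWRSSIDY",
  "CNCRFLHSSCNRSESKNHNFDFAMHGRQLWENKEWAFCAFWSQCPDSCMKMIEMPQVKMQ",
  "IYDCFGWYDWMPNVAQNTFIVERIVNWTHGAYHWIGNENNHVRRPPPQVPQIWQSPSQRD",
  "VDDAMEFSTFRHPYQVLANCSSMVASNWVYSIRRVVANAGMFYCLMDVNVAYLKKNTKVV",
  "GCAIAHEMLHTDDITLRDAWPMEACFDRRSWSLFRLTCAPFKGNVNYWYYWIWRGDTSIY",
  "NHPFPDCFMGTMADWSQVYGFPSRLMTADNNMVFPAAFTQDLPHVFYPVPCNTVFSPVRG",
  "PAHNDECVKGECLYDEEHHW")

SHC_TEMPLATE <- paste0(
  "DKEYGINMSPNENVQALSKWNIWIMNAMHKYAVYSWIKGNMYSWGYIPRKFEPQNTRCQL",
  "CAAEHIEGLAYHRVSLNLHHNTCQDWTMLIDHFQENLWMYFVMQYADQREYPHHFPHCVE",
  "VDPPLVNYFRNGVQYIEPWAFEMWPLDDLARYCTWVHMPYIHYACASWMGKPSVFWWEKV",
  "VPHKWQRHSPEEEWVTNMNIVPRGILLRGLHWRSAYIHWPGFINYWECCRRPTTMHADGA",
  "QRPFSVSKVQIKMVQKCWEPKIHAGEAKWTLSFEQVWHNKGLVTTFKNTVPVAIGTNHQD",
  "IDDHNNSGRKHTQHVYIAMNVDINESQRQCIHIEPARHVNWDETAMPYVFRKYSIVIIQF",
  "NMHFWRGYPARAVAKQEVMHLEENQPMTWIAFFWGYMQQNPGCMIMCNSKFMLNKADYDR",
  "NLPELNEFGYVYNDVCWFCPKSGKRMWLSWYNNMCNPMVAWAEALMRKYLCHELRFVGHH",
  "QTHRHLVMEAAIIILWVVRY")

# the 20 standard amino acids
.AA20 <- strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]]
.AA21 <- c(.AA20, "X")

# planted coordinates (1-based, template-local) and mutation-locked spans
.TEMPLATE_INFO <- list(
  alpha = list(
    length = 300L, ddxxd = 100L, nse = 240L,
    ile_bact = 216L, pix = 219L, ile_plant = 220L,
    locked = c(100:105, 216L, 219:221, 240:248),
    aberrant = list(list(at = 100L, txt = "DDTFQD"),
                    list(at = 240L, txt = "NGLISVVAE"))
  ),
  gb = list(
    length = 500L, lhs = 186L, dyad_his = 187L,
    pnv = 252L, dyad_asn = 253L, dxdd = 300L,
    locked = c(186:188, 252:254, 300:303)
  ),
  shc = list(length = 500L, dxdd = 300L, locked = 300:303)
)

#' Packaged template sequences
#'
#' The three fixed amino-acid templates underlying the synthetic-proteome
#' generator and the internal profile scanner: a Class I terpene-synthase
#' alpha domain (300 aa), a Class II diterpene-cyclase gamma-beta didomain
#' (500 aa) and a squalene-hopene-cyclase-like decoy (500 aa). Catalytic
#' motifs (DxDD, DDxxD, NSE) and active-site contexts (LHS, PNV, PIx) are
#' planted at fixed positions; see [templatePositions()].
#'
#' @return A single amino-acid sequence as a character string.
#' @export
alphaTemplate <- function() ALPHA_TEMPLATE

#' @rdname alphaTemplate
#' @export
gbTemplate <- function() GB_TEMPLATE

#' @rdname alphaTemplate
#' @export
shcTemplate <- function() SHC_TEMPLATE

#' Planted motif coordinates of the packaged templates
#'
#' @return A list with elements `alpha`, `gb` and `shc` giving the 1-based
#'   template-local positions of every planted motif and the mutation-locked
#'   spans the generator never diversifies.
#' @export
templatePositions <- function() .TEMPLATE_INFO
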