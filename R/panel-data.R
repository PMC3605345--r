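# Bundled synthetic reference peptide panel (generated once, frozen).
# Synthetic stand-ins for chromoviral gag-pol domain exemplars: each clade
# variant derives from a shared scaffold with canonical catalytic motifs
# (CCHC, DTG, LPQG/YIDD, DEDD, HHCC + DD35E + GPF/GPY) pinned in place.
# Not natural sequences; see ?chromo_reference_panel.

.panel_peptides <- list(
  CRM = list(
    GAG_ZF = "NQLQCKVCYKYDINTDDHMFNCTMEMNFSTGNAVQNEEIDPCRFDIVWLRRDNCQAVDCC",
    PR = "WTPMFDCVGCQKTGFMHDSNQGCADTGSAETIESRPSQIMMYSNLFTFWYINYRQVYEFETWSMLFRGERTVHAFKPMQW",
    RT = "FRMDLQGPRNLYYFCETRLIINIAHQPIIDGQDHVDMVNQHRKFWHVGCIIRKVIALVRRCKEQHIDWRHPRFRQLNTNGVWLYLGFAYIWWKHAEATMCYTMKRVLPVLPQGMEPERQILTLNRCMVAAFSTNINTLKYPLIANTGNAYIDDEWLMEQYQIWYDGNHQPMILMHGEEEWGLQCPDTKCIHTRFMPMWLWAIGIMKHCWSGSMMDVLSACADMIHVTNPCQATRRTCSDL",
    RH = "TSDTWSAGYDRNYVQDAHNGSRNHRSEFKNIVGFVSAVRGYWRLERFAMGVCQGQCTTWHFYGCWVSMEDVNFYKLEIWRPEGMAGHFFSDDSNRAENLDDPAAWAHLLI",
    INT = "FAGAHAADHWRNLTNFQSPMNCYIACRGVLCQQDFFGNEHIWHCVVACMKPQCCNHCHVPPKNSGQCIHAVCRQVGEVLMSCQTCRQNPCSVWCTNSVNASKWGFVLCDHINFDKIETQDHVAGSHQPASRFDEMMQKQVRQHMDTPQINCGCAGQDLQSPAHALDYDDYVHHIRVGWRPTEFLCRTTLLVTEPRLGKKDIRVPGAKWLSEMQIALRLRPNKAKQFMYRVFHSECYTEVMKHMPFGSNWQDWNDEDPTKVDIPLAFITFHYFGHWQQVRMGPYNSFKCGYAFLFECEPVC",
    CD = "WDMDWYMMHHHPCFVTYVYWQICTKSKGMPHSAQKVWSRYNYYPCRVCHL"
  ),
  Tekay = list(
    GAG_ZF = "NTLNCKMCYDYWENTIDHMFNCQIAMNFSTGHAVQNPEIDPLLFDIVWLLADNCQAVDCC",
    PR = "MDPMIDLVGCAKTGMFWYSNQGKADTGSAETIESRPSTIKMYSNFFTFIYINYEQGTECETWSHLFRGEAVVCALKPMQW",
    RT = "NLMDLQMPRNLYAFHERVHIINIAHQPIIPGQDHVPMVNQRVHFWHVGCYIYDVEWLWRRYKEQHIDDRHARIEQLNTNGMWVYLGFAYNNWRHAEATMCFTMKRVLPVLPQGTHAETQILTNCRCFVAAFSGNINTAKYPLMADTGNAYIDDESLPEQYQIWIDGNHQDMILNHGEECKGPWPVDTSCIHTRFMPHWLWAIGIMEHCIMGSMMGVLCACTDMIYTTHPCQQWRRICSDY",
    RH = "TSDTISGGYDRNYEIDQLYELRNHRSEMKNIVGFSSQHMGYRRLEMDANGVCQGQYSTCHYYGCAVSMEDVNFYKLEIACIEAMAGHFKRDDSNRAEFADDQYAWAHLLI",
    INT = "FAGAHAADHWRNVTNFQSPTNCYTACHHVLCQQDQFGNSHIWHCVLADMKVQCYNHCHVPPKNSGQWIHIVMRGLGEPFMSRQTCFQNWCGVWCTNAVDASKWGFVLLDHINFDNIETQDHVGFRHQWASRFDEMMQKDVRQHADTPMLCCDCAGQDLQSPAHRLDEHDNVHEDEVDWRGFPFLSWNTHLVTEPYLGKKDIQCPGAKYLEAMQLALRLLPNKAVQYTYPVFHSEPYPEVMTHNTCGSNWQDWILEDPLKVDIPMAFCTFHYFGHWMQVIIGPFNSPKCGKAFHFECEPVE",
    CD = "YDMIWGYWKVSHCEVYYRWHTICAWLKGMIHSKQIVHSVSNYVVCRELFL"
  ),
  Reina = list(
    GAG_ZF = "NTLQCKVCYFYSINVWDHMFNCEMCMNFSTGNAGQNVEIDPCLFDKVWLLRDNCQAVDCC",
    PR = "MGIMIDLVGCAKTGFHWDSCQGCADTGVAETIESRPSTIWMYSNFFTFWYINYCQVYECEPWSMLFRGIAVAPADKPMQW",
    RT = "FLMDLQGPRNLWYFHELVLIINIAYEPIIEGKDHVPSVNQRVHFWHIGCIIRDVEALVRRCKEQHGDWRQARFTQRNYNGVGLYLGEAYNNNRHAEATMCFTMSRVPPVLPQGMHAETQILTNNRCWCAARSWEINTAKYPLMANTGNAYIDDDWLMEQYQIWYDFNHMDHILMHGEECRGKFCVTTKCIHTRFLPHPLWAIGIMSHCWSGSMMDVLSDCEDMIYVTHPCQQQRRGCSDQ",
    RH = "TSDTISAGYDRNYEQDQHYESRNHRQEFKNIIGFFSQVMWYVRTEMDAMGVCQGQCSTCHMYGCNVQMEDVNFKKCEIWAMPVMKGHFFRDDSNRAENLDDQYAWAHDLD",
    INT = "FIIAHLADHTRNLTNMQSPMNCYTACWGQLCQQDQRGNGHNWRCVLADMKPQCCMHCHVPPKNSGQHIHFVDRGLGEHLMSRQTCRQNWCSVWCTNSVFASKWGFVLCDHINFDNIETQDHVAGRHSYASRFDTMMQKDQMQHADTPQVNCDDAGQDLQSPAHRLKEMHYVHHNRVDWRGNEFLCRTTGLVTEPYLCKKDIQVPNAKWLEAMPLALRLLPNHAVQYTYRVFHSEPQPEVPKHNWFGSNVQKWILEDCTTVDPPLAFCDFHYLGHWPQVRCGPFKSPKPGYAFHFECEPVE",
    CD = "YDMWWYAMKVSPCFLYYVWQRDCAWWKGMIHWMKKVHSVSNYVVQREEHL"
  ),
  Galadriel = list(
    GAG_ZF = "NTLQCKVCYDYCINTIDHQFNCGMEMNFSTGNEVQNEEIDPCLFDIVWLLRDNIQAVDCC",
    PR = "MDPSIRLVGDARTYFHWDSNQGCADTGSAETIESRPSTIGMYSNFFTFWNINDRIVYECETWSMLTRGEAVVPTLKPMQW",
    RT = "FLMPRQYPQGLYYFHETVLIINIAHQPQIEGQEHVPMVNDRGHFWHVGCCIGDVEALVRRCKEQHIDWRHARFEQLNTFGVWLYLGFAFNNDRHAEATMCFTMGRDDPVLPQGLHAETQILTNNRCFVAAYSTNINTAKYGLMANTVNAYIDDEWLMGQYQIWYMGNHQDMILMHPEECQGDCCVDTKCIHTCFMPLWLWGISVCWHCWSGYMMDVLSACEDMEYVERPCQQWRRTCSDA",
    RH = "THDTISANYDRNYEDDQHYESRNPRSEFKWIVGFSKQVMGYVRLEMDAMGVCQGQCSECHFYWEFVSMEDVNFYKLEIWCIENMAGVYFRDQSNGAENLDDQYAWAHLLI",
    INT = "FAGAHAHDHWRNHTNFESPMNCYTDCWGVLCQQDQFGNSHIWHCVLADMSLQKCNHVHVPPKNSGQWIHIVHRGLGEVLMSRQFCRQNQPSAWMTNSVNATKWGFVLCDHINFDNIYTWDHVSGRKQPASRFDVMMQKDVRQHADTPEIPCDCAGQDLQSPAHFLDEMDYVHYNRVDWRGPEFLCRTTLLVTEPDLGKKDIQVPGAKWLEAMPLALRHLPNKAVQYTYRVFHSEPMPEVMKHNPFGSNWQDWNLEDFTKNDIPLAFCTFHKFGHWPQVRMGPFNSPKCMYAFHLECEPVE",
    CD = "YDMIFYYMKVSPKFVYYVWHTICAWWKGMIHSMQKYCSVSNYVVCRELHL"
  )
)

.hp1_chromodomain <- "YDMIWYYMKYSPCFVYYVWHTICAWWKGMIHSMQKVHSVYNYVVCRELHL"
.hp1_cage_columns <- c(10L, 25L, 40L)

# integrase sub-profile windows (columns of the INT exemplars)
.int_zf_cols    <- 1:30
.int_dd35e_cols <- 112:198
.int_gpfy_cols  <- 264:283
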