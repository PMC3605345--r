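>CRM_GAG_ZF synthetic exemplar
NQLQCKVCYKYDINTDDHMFNCTMEMNFSTGNAVQNEEIDPCRFDIVWLRRDNCQAVDCC
>CRM_PR synthetic exemplar
WTPMFDCVGCQKTGFMHDSNQGCADTGSAETIESRPSQIMMYSNLFTFWYINYRQVYEFETWSMLFRGERTVHAFKPMQW
>CRM_RT synthetic exemplar
FRMDLQGPRNLYYFCETRLIINIAHQPIIDGQDHVDMVNQHRKFWHVGCIIRKVIALVRRCKEQHIDWRHPRFRQLNTNGVWLYLGFAYIWWKHAEATMCYTMKRVLPVLPQGMEPERQILTLNRCMVAAFSTNINTLKYPLIANTGNAYIDDEWLMEQYQIWYDGNHQPMILMHGEEEWGLQCPDTKCIHTRFMPMWLWAIGIMKHCWSGSMMDVLSACADMIHVTNPCQATRRTCSDL
>CRM_RH synthetic exemplar
TSDTWSAGYDRNYVQDAHNGSRNHRSEFKNIVGFVSAVRGYWRLERFAMGVCQGQCTTWHFYGCWVSMEDVNFYKLEIWRPEGMAGHFFSDDSNRAENLDDPAAWAHLLI
>CRM_INT synthetic exemplar
FAGAHAADHWRNLTNFQSPMNCYIACRGVLCQQDFFGNEHIWHCVVACMKPQCCNHCHVPPKNSGQCIHAVCRQVGEVLMSCQTCRQNPCSVWCTNSVNASKWGFVLCDHINFDKIETQDHVAGSHQPASRFDEMMQKQVRQHMDTPQINCGCAGQDLQSPAHALDYDDYVHHIRVGWRPTEFLCRTTLLVTEPRLGKKDIRVPGAKWLSEMQIALRLRPNKAKQFMYRVFHSECYTEVMKHMPFGSNWQDWNDEDPTKVDIPLAFITFHYFGHWQQVRMGPYNSFKCGYAFLFECEPVC
>CRM_CD synthetic exemplar
WDMDWYMMHHHPCFVTYVYWQICTKSKGMPHSAQKVWSRYNYYPCRVCHL
>Tekay_GAG_ZF synthetic exemplar
NTLNCKMCYDYWENTIDHMFNCQIAMNFSTGHAVQNPEIDPLLFDIVWLLADNCQAVDCC
>Tekay_PR synthetic exemplar
MDPMIDLVGCAKTGMFWYSNQGKADTGSAETIESRPSTIKMYSNFFTFIYINYEQGTECETWSHLFRGEAVVCALKPMQW
>Tekay_RT synthetic exemplar
NLMDLQMPRNLYAFHERVHIINIAHQPIIPGQDHVPMVNQRVHFWHVGCYIYDVEWLWRRYKEQHIDDRHARIEQLNTNGMWVYLGFAYNNWRHAEATMCFTMKRVLPVLPQGTHAETQILTNCRCFVAAFSGNINTAKYPLMADTGNAYIDDESLPEQYQIWIDGNHQDMILNHGEECKGPWPVDTSCIHTRFMPHWLWAIGIMEHCIMGSMMGVLCACTDMIYTTHPCQQWRRICSDY
>Tekay_RH synthetic exemplar
TSDTISGGYDRNYEIDQLYELRNHRSEMKNIVGFSSQHMGYRRLEMDANGVCQGQYSTCHYYGCAVSMEDVNFYKLEIACIEAMAGHFKRDDSNRAEFADDQYAWAHLLI
>Tekay_INT synthetic exemplar
FAGAHAADHWRNVTNFQSPTNCYTACHHVLCQQDQFGNSHIWHCVLADMKVQCYNHCHVPPKNSGQWIHIVMRGLGEPFMSRQTCFQNWCGVWCTNAVDASKWGFVLLDHINFDNIETQDHVGFRHQWASRFDEMMQKDVRQHADTPMLCCDCAGQDLQSPAHRLDEHDNVHEDEVDWRGFPFLSWNTHLVTEPYLGKKDIQCPGAKYLEAMQLALRLLPNKAVQYTYPVFHSEPYPEVMTHNTCGSNWQDWILEDPLKVDIPMAFCTFHYFGHWMQVIIGPFNSPKCGKAFHFECEPVE
>Tekay_CD synthetic exemplar
YDMIWGYWKVSHCEVYYRWHTICAWLKGMIHSKQIVHSVSNYVVCRELFL
>Reina_GAG_ZF synthetic exemplar
NTLQCKVCYFYSINVWDHMFNCEMCMNFSTGNAGQNVEIDPCLFDKVWLLRDNCQAVDCC
>Reina_PR synthetic exemplar
MGIMIDLVGCAKTGFHWDSCQGCADTGVAETIESRPSTIWMYSNFFTFWYINYCQVYECEPWSMLFRGIAVAPADKPMQW
>Reina_RT synthetic exemplar
FLMDLQGPRNLWYFHELVLIINIAYEPIIEGKDHVPSVNQRVHFWHIGCIIRDVEALVRRCKEQHGDWRQARFTQRNYNGVGLYLGEAYNNNRHAEATMCFTMSRVPPVLPQGMHAETQILTNNRCWCAARSWEINTAKYPLMANTGNAYIDDDWLMEQYQIWYDFNHMDHILMHGEECRGKFCVTTKCIHTRFLPHPLWAIGIMSHCWSGSMMDVLSDCEDMIYVTHPCQQQRRGCSDQ
>Reina_RH synthetic exemplar
TSDTISAGYDRNYEQDQHYESRNHRQEFKNIIGFFSQVMWYVRTEMDAMGVCQGQCSTCHMYGCNVQMEDVNFKKCEIWAMPVMKGHFFRDDSNRAENLDDQYAWAHDLD
>Reina_INT synthetic exemplar
FIIAHLADHTRNLTNMQSPMNCYTACWGQLCQQDQRGNGHNWRCVLADMKPQCCMHCHVPPKNSGQHIHFVDRGLGEHLMSRQTCRQNWCSVWCTNSVFASKWGFVLCDHINFDNIETQDHVAGRHSYASRFDTMMQKDQMQHADTPQVNCDDAGQDLQSPAHRLKEMHYVHHNRVDWRGNEFLCRTTGLVTEPYLCKKDIQVPNAKWLEAMPLALRLLPNHAVQYTYRVFHSEPQPEVPKHNWFGSNVQKWILEDCTTVDPPLAFCDFHYLGHWPQVRCGPFKSPKPGYAFHFECEPVE
>Reina_CD synthetic exemplar
YDMWWYAMKVSPCFLYYVWQRDCAWWKGMIHWMKKVHSVSNYVVQREEHL
>Galadriel_GAG_ZF synthetic exemplar
NTLQCKVCYDYCINTIDHQFNCGMEMNFSTGNEVQNEEIDPCLFDIVWLLRDNIQAVDCC
>Galadriel_PR synthetic exemplar
MDPSIRLVGDARTYFHWDSNQGCADTGSAETIESRPSTIGMYSNFFTFWNINDRIVYECETWSMLTRGEAVVPTLKPMQW
>Galadriel_RT synthetic exemplar
FLMPRQYPQGLYYFHETVLIINIAHQPQIEGQEHVPMVNDRGHFWHVGCCIGDVEALVRRCKEQHIDWRHARFEQLNTFGVWLYLGFAFNNDRHAEATMCFTMGRDDPVLPQGLHAETQILTNNRCFVAAYSTNINTAKYGLMANTVNAYIDDEWLMGQYQIWYMGNHQDMILMHPEECQGDCCVDTKCIHTCFMPLWLWGISVCWHCWSGYMMDVLSACEDMEYVERPCQQWRRTCSDA
>Galadriel_RH synthetic exemplar
THDTISANYDRNYEDDQHYESRNPRSEFKWIVGFSKQVMGYVRLEMDAMGVCQGQCSECHFYWEFVSMEDVNFYKLEIWCIENMAGVYFRDQSNGAENLDDQYAWAHLLI
>Galadriel_INT synthetic exemplar
FAGAHAHDHWRNHTNFESPMNCYTDCWGVLCQQDQFGNSHIWHCVLADMSLQKCNHVHVPPKNSGQWIHIVHRGLGEVLMSRQFCRQNQPSAWMTNSVNATKWGFVLCDHINFDNIYTWDHVSGRKQPASRFDVMMQKDVRQHADTPEIPCDCAGQDLQSPAHFLDEMDYVHYNRVDWRGPEFLCRTTLLVTEPDLGKKDIQVPGAKWLEAMPLALRHLPNKAVQYTYRVFHSEPMPEVMKHNPFGSNWQDWNLEDFTKNDIPLAFCTFHKFGHWPQVRMGPFNSPKCMYAFHLECEPVE
>Galadriel_CD synthetic exemplar
YDMIFYYMKVSPKFVYYVWHTICAWWKGMIHSMQKYCSVSNYVVCRELHL
>HP1_CD synthetic HP1-like chromodomain (cage cols 10,25,40)
YDMIWYYMKYSPCFVYYVWHTICAWWKGMIHSMQKVHSVYNYVVCRELHL
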