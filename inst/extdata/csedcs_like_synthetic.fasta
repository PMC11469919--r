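>CPSKS_REF_SYNTHETIC
NNQIYQMMWQTQIPGSLGEIMTPYGEPVLPRCCMKKGQDGLRWHIIGSEHRSENILYLSE
CTCMLFWHWYPDPVTWKGYYVWCAVGSKLRMAWAIQKIWNVFWYECHKPDNDWGSPPWGT
EGLGTQQSWMSASGHQEKKDSCKGIPYTLKATYVHTHQPDMHEHVYDLCYAAIWRSSIDY
CNCRFLHSSCNRSESKNHNFDFAMHGRQLWENKEWAFCAFWSQCPDSCMKMIEMPQVKMQ
IYDCFGWYDWMPNVAQNTFIVERIVNWTHGAYHWIGNENNHVRRPPPQVPQIWQSPSQRD
VDDAMEFSTFRHPYQVLANCSSMVASNWVYSIRRVVANAGMFYCLMDVNVAYLKKNTKVV
GCAIAHEMLHTDDITLRDAWPMEACFDRRSWSLFRLTCAPFKGNVNYWYYWIWRGDTSIY
NHPFPDCFMGTMADWSQVYGFPSRLMTADNNMVFPAAFTQDLPHVFYPVPCNTVFSPVRG
PAHNDECVKGECLYDEEHHWGSGSGSGSGSWEVYPHHLHNWMARVAREADWLSPRFPSGT
VAFDDMSNVWGITRQKFPHEFCANINQFYVEVEHSFKDSEHGMCFFTHFPTFFTVLAMWS
LMSFSQSCGDDTFDQVYYQTNNVQLGEDLARFLQGTKEFPYFIHVLTMPVKEKHIHVFPR
ESITDDKNINLGFAYVPFLICMAYVDSTRHDWAELCQQSMRKYEWNTDGLWPRYIDDMLA
TVYLEIQPPILNRWHFICGGLAELTVYYVNDLISVVAEQVWFAAFHQKCTEYYPHISTHM
WIDNCDYCKDMIWLKVPYVVITFGWNGSCH
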