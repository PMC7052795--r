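LOCUS       CE_sfGFP         2806 bp    DNA     circular SYN 11-Sep-2026
DEFINITION  CE_sfGFP
FEATURES             Location/Qualifiers
     misc_feature    1..3
                     /label="CCA"
                     /loop_kind="scar"
                     /junction="TRUE"
     misc_feature    2045..2064
                     /label="UNS1"
                     /loop_kind="UNS"
     misc_feature    4..23
                     /label="UNSX"
                     /loop_kind="UNS"
     misc_feature    44..643
                     /label="ampicillin"
                     /loop_kind="marker"
     misc_feature    2065..2067
                     /label="ACT"
                     /loop_kind="scar"
                     /junction="TRUE"
     CDS             2079..2795
                     /label="sfGFP"
                     /loop_kind="CDS"
                     /partial="TRUE"
ORIGIN
        1 ccagtttgga tcttccagtc caatttggtt gcataaggcg aagggactct ccgactcgag
       61 acgagcttaa ctttacccgg acatcctgca ctatataggg atgccccggg gtttgaaatg
      121 ggaaattttc gctaacttgg taatttgtcc gtccagcgtt gcctacgatt ggctctcagt
      181 attcgggcga ctggggtatg aagaggtaat caatggcccg atgcttcacc tcctcggtaa
      241 cgcgccttcc ctgaccgtac tattgtgcgg cggtatggga catacacaat gctcgcggac
      301 ctatgtgtga ggtcgtccac ggtatgactc aggtttagtt catctaatta aaacgcgcct
      361 tgctacgtgg acagaatcat tacatcacgt gcagtgttat ctgtgacttg tatttatgaa
      421 tcgtcgactc ctatactaat agttatcatt caatggaaac agcctagtgc gcaacaatca
      481 cgcacatagc tgtggaagcc ccagccaaag tggggtgtcg aaggggcggc acacaacaca
      541 tttttatatc tagggacccc ccatgacccg aacagcctga gcgctgtctg cgcctcgaaa
      601 tgttcccagg aatcgaccta gcgtgcttag attatctgag tcgtagatac cgtttcctgt
      661 tgataagccg tacagatttc cagcgaggct ctatgtgaag gatctcatcg gttggtaaag
      721 ccttgtaaat actacgtggc ttcataacac ggcacgcagt gcttattaac tgccgctatt
      781 gatgagaacc ttgggggtta cctccgagat agtgttggag ctaagtgatt acgacggttg
      841 gctctcagaa gatccacata tagtgaaagc ggcctagtgc acttacgcga agccaaagat
      901 ccatcgagtc tgttatcctc aagctggaca ggctaaaatt gacgtatttg taaacgtaca
      961 aggataccgg cttaattgta aggaggtact caagactcgg catgaaggga tatcaagtcg
     1021 tacaacgaca ctcaggttcg tggtcctgga cgaggtccaa tccgaggata acggctgttt
     1081 ggcggaccga atggaaaggg acctactctg gcaaatcaac tttaaaccct tgataccttt
     1141 ctgctctcac actgctacta aacgcacata ccagaaattc agtcccttga tgagtgacgc
     1201 ccgtttgggt caatcccctg cagtggcgcc accaaatacg ttagcagatc accgataaag
     1261 tcagagctag cttgaggatg cagcaatgcc ctatatcgta cctaataaac ctgaaaatgt
     1321 cagcgcgtag aggtggacat aagatctacg gctttcggtc ctagcggatt cccaattcgt
     1381 cccgatccat taacgaccat taaataagat ccgctcaaga tgctgttaat atactttctg
     1441 gatagaaagc gcccgatacg tatcatactt tctctcgttc gcgatggaac caacgtatgc
     1501 ccttatccct agcaatgtgg agtctttcgt gacggggctc accaaatacc tacaatcgcg
     1561 tgggtgtcgt tgtgatatgg tttgtagatc ggattagctg ccatacatac tcccgtttta
     1621 gcgtgcgttc ggacccggca agacctcgta tcttggttat gagacggatc ctggtcatcg
     1681 ttagcttgcg cacgaggata ggtaacgcca gtcctagctg ccttctggga tgatcttgtc
     1741 tgctaataag gtttaataga cgtacggggc caatcacacc acttcggaaa aggtccgggt
     1801 attctctcgg ataaaaactt cgttgacgtc agagaaaggc tgtttgcatg aacctgtcta
     1861 aggcgccaca aacgtgtagc caggcaggtt ggcgatgcct tcggaggggg caacaagaat
     1921 cttagtatta gacatggtgc cctctcccgt cgaaaccagc tctccggaac ccacggtacc
     1981 tacgtatgaa ttatgtataa gtctgctcac gtggcactga tcacactggg atgaccaggt
     2041 cacacattac tcgcatccat tctcactggt ctcaaatgaa gaggctcatg ccttcgacaa
     2101 ggattacggg aactccggat tggtcagcta atagaccacg attgtatagt gtcgcttccg
     2161 atatagccct ctggacctcg gatgggatat ggctgtctaa tgtgggttat gcggaactca
     2221 cactggtgct accgtgttat ctcagtctta cgagcgtgtg ccaggctcag caccgaccat
     2281 ttttgcatca agagcggaat caccgagttt cagtacccac gccaccggtc tggtattctc
     2341 gtacccgcat aatgaacctt cagtgttcta ccttaaattt tagattcggt ggggcaatag
     2401 gcaagctgca cgcctcttcg ttgggaatta cttcgtggct gacggtaaca aaccggcaag
     2461 cctcgcgtat gcgccgggtg ccaagtcctc caagggcttg cattgggcat ctagatcttt
     2521 gcttagcggg cacggtcgct cctgtcatag ataccgcgcc tgcaagcttc gaccttactc
     2581 cggaaatttg cggacgctgt acccatcagc ttcaatccgt acagatccat aacagcctat
     2641 cccaaaatag gatttgtgct agaaccgccc gctccagttc accttcgcac acatttacat
     2701 acttagtgct taagctggca tgggaacgtg gttgtgctag cgcgttacca agcgcggacg
     2761 gggcatcgtg gatatactcg gatccttgcc cataagctta gagacc
//
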