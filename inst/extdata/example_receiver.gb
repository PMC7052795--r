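LOCUS       pCAo-1           3400 bp    DNA     circular SYN 11-Sep-2026
DEFINITION  pCAo-1
COMMENT     built receiver pCAo-1 on pCA_backbone
FEATURES             Location/Qualifiers
     misc_feature    1..20
                     /label="UNS1"
                     /loop_kind="UNS"
     misc_feature    43..342
                     /label="lacZ"
                     /loop_kind="dropout"
     misc_feature    365..384
                     /label="UNSX"
                     /loop_kind="UNS"
     misc_feature    405..1004
                     /label="kanamycin"
                     /loop_kind="marker"
ORIGIN
        1 cattactcgc atccattctc gctcttcaat gggagagaga ccataaacga cttgaatctc
       61 agtatgggcc ataaccatca gcgatgcgcg cgcctcgagc ttctatacaa accgtgctcc
      121 aggtgcgagg cacttactca agcatccgaa tccgtacaaa aatccggtta ctcgattgaa
      181 gtttctggac gggttaaaag tctgttatgc tgatcgtaat gcgaccacaa ggggagcacc
      241 acagtcggtt tactattctt cggtttaatc atgcttgcag aaaccccgtc ttcagccgag
      301 gttgtaagtt tctacgagct ctcgtacttc ggtgctggtt atggtctcac gctgcaagaa
      361 gagcgtttgg atcttccagt ccaatgacag gccggaaacc ccgagaaaac aacccatgat
      421 gccccgtttc tagcattagt ccggccttcc accccaggtc ggtctggata tatagctgaa
      481 tcatttaaag caagggccct gtcctggtga ccaggcgcat ctatggtatc tagcggaacc
      541 cttaaacagc ggcggtaatc tcacgggggt atgatgtcta tgatcacccg acggggcgag
      601 ttactctcgt aataggaatc ctcttgcatg tacatgaagt gattaaaata atcccataac
      661 cctccactcc tctaattgtt actaaaagac cctgagaaag agcattggtt ctagcttatc
      721 gtattcccaa ttaacatatg cgagcattat cggggctatc aagctgggcc agtgatcagg
      781 aacaagcgtt agaggcattc aagcctgaag caggagcatc cttcttacat aaccagcttg
      841 ggattgtata ttacactgag aagtagggtc aacgtgctga gttgggaagg ataaaaggta
      901 ttcgtggcca cgctccaaaa caactcaatt agtcctactt gtgacataca attaatccgc
      961 ataccatagt gttagccgtg attgacaatg cccagggtcc catgtgagga tcacgtgtcc
     1021 cacataccct gttagcgttt tgtgtccagc gaccgatttt caacgtcagt agcgtgacgg
     1081 tttttctaag acaaggcttg cttacttcat ggcaaatacc ggttgcaggc aacgctctgc
     1141 ggagctcggc aattcacaaa gcacagacaa gcttaagaac actgattagt tagagaaaac
     1201 tttacttcgt cgtcccgcca ttgttcgata gtgcaactac cctcgcagag acgtgcattt
     1261 aattcatgcc ggggaattac ctgttattcc ctgatttaca tcgatcacaa gtagcagcct
     1321 cgcgtacgca acactaccgc agtcctgaat cctttcaacc tatgtacgag gtaaaagagc
     1381 gggttggagt tacatccccc gcgtcgacgc gatgcaacaa cactcctaat caacagttgt
     1441 gactcttagg cacaatgact cccttcccag gaaactcaat gtccgccagt ccgagggttg
     1501 ccttaggatt agcatgactg acgcgaatgc gcctggtggc cctgttttga taccgcagtc
     1561 tttagctgac ggacttgcgt gtaatgtacg gctccggtat tcggcgcaaa gtaccttggc
     1621 ctatataagg tctaagcaat gttatgtcca gaccagcgaa acttctcagt aagagctcgt
     1681 ggattgattc ccatattggt gcgccgctct ttaagttttg taccattcag ataaggttgc
     1741 agaaggctca acttgttccc ctgttcagat agtaggtgca ctcgtcaggc caagtctgtc
     1801 gagagtaccg aaatcattcg cgccgtcgaa tgacgggttt ttgaatagca taaaactatc
     1861 caatttcacc gaaattccag cggagcggcc tacttggaag attcgcacat tttgcgagtg
     1921 acggaacgag tcttgaaggg gcgggcgtgg agtaaaaaag actattcata tttgcgataa
     1981 agatggatgc acatcgacat aaagtgtggg ggatcgatgt cgtacaccct tgcgcagtat
     2041 catctctggg ccaggctacc aagcggagtt caggggcgcc ggagctgtac taacgaattg
     2101 caacactaga aagtcggtct acctccacaa agctaattgg atttgaatac aatgcggcat
     2161 tgcgctaggg gttcgccaga aatcgatcag gccaattttc gttccgtaca cgctcgccga
     2221 tccgtttact tgttcgttgt tctattaagc cgagccaaag ggttacgtta cttgaccggt
     2281 cgcgctgctt gtgatccctc tgtgggagcc aggaatagct tacgatactc ccatgcgatg
     2341 gaacacgctg atcgcaggta taggtacgtt gccacgtgag gacgggggcc tatgtatcgg
     2401 acgtcgggcg gcgttcagac caccccccat ccttgtgtgg cgccgccttt atgataatcc
     2461 gctcacctta ccgactaagc ataccccaga ccaatcttct tggtagaaca gttctgcaat
     2521 gcaggaaacg tggacatatt acaacccgcc ctattgctgg gcgactaaga caccatgttg
     2581 ccatgtgtct gactataatt tatataccag aaactgactt gaactacagg ccccatcagg
     2641 ggcccttcat cttggtgacc aagaatctat tagcgctctc tgcttatacg acggtgtcgt
     2701 cccgccttga attggcggtt gacgttgcta aagcccggga gtcgcattat gaagtgaggt
     2761 acgttctacc atgggcactt catggtttac tgtgcacgcg agcaaggagt gtaggaccat
     2821 aaccatcgag ctacatggca ctccgatcgc taacgtcacc tagctagaga tagcctgttg
     2881 gatcgacttt aacagaacta tgccatgggc agctccgagg tacatgctag tccgtgtgag
     2941 aagtacacct cgtaaatagc cccttagttg tttacatacc tactgtaagg tgcagtagca
     3001 tccttcaaca agccaaaggt cggtgatcaa gttagacttg ccgctagggt ttcagcgtgc
     3061 aacttccgga tatcacgtcg atcattgatt tgttgccaga acacggtatc gggtgacgaa
     3121 gtcctctcgg ggcacaaaat tgcgaattag gaagacttga atggggttag cgcgaagtat
     3181 gcgctcactc gaccctctct taagctgctc aagaagataa acggtaaaag attgtttcat
     3241 gaacaaaacc gctattgcat acgtgcttat ccgtaatctt acccctctac ggtgatacat
     3301 taggctccgc tcagaaaccg aattgccacg ctctcgtttt agtgttatat gaacaaccag
     3361 aacgatcgca ggaagcgcct gtcgaggcaa ccaatccctt
//
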