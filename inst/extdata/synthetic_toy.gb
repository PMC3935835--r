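LOCUS       TOY001                   240 bp    DNA     circular UNK 01-JAN-1980
DEFINITION  synthetic toy genome for parser tests.
ACCESSION   TOY001
VERSION     TOY001
KEYWORDS    .
SOURCE      .
  ORGANISM  .
            .
FEATURES             Location/Qualifiers
     source          1..240
     CDS             10..39
                     /gene="toyA"
                     /locus_tag="t0001"
     CDS             complement(61..90)
                     /gene="toyB"
                     /locus_tag="t0002"
     CDS             join(101..110,121..128)
                     /gene="toyC"
                     /locus_tag="t0003"
     CDS             140..149
                     /gene="toyD"
                     /locus_tag="t0004"
ORIGIN
        1 gctaaagaca attacataac atacacgtca gcacgaaact tgttggccca gtgtgaatcg
       61 cttaagggtt aagtaagtgt gatgcatacg cctttacttg ctgtgtccac cccatcggac
      121 tggcattttt attacactca gaaacagaac tcgggtaatt ttgacaggtc acgcagaggc
      181 gcgccctcct gaagtgcgtg gacactcgct atgaatctct gatttaccca ctctgccaaa
//
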