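>synthetic_H6TQS9_standin synthetic 200-residue RubisCO large-chain-like fragment (composition-matched stand-in; not a database sequence)
QHVFDYSLDPKPHAKHWLKYQLWHGYEQTFSIEPGFGAQRETGMTMNDMREETIGSPLAY
PWSYFAVFPAGLAKAPGEYGRLEDIYALGVDGAHHSEYSRDAAEHMSSYGRFSTYYGERF
ETRRPEQMASQRDHFRFLSDLGKISFLHVLPVIEPIAGLPHYRAYATVLASTTKTLFRII
QNVASSQILVAILLGGYLSS
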