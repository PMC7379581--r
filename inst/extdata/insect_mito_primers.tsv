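name	fwd_seq	rev_seq	expected_len
Hex12SF2-Hex12SR2	ACTWTGTTACGACTTDTY	AGGATTAGATACCCTDBT	391
Chiar16SF-Chiar16SR	TARTYCAACATCGRGGTC	CYGTRCDAAGGTAGCATA	348
HexCOIF4-HexCOIR4	HCCHGAYATRGCHTTYCC	TATDGTRATDGCHCCNGC	322
HexCOX2F3-HexCOX2R3	GGNCRHCARTGRTAYTGA	RATYTCDGARCAYTGNCC	260
HexCytBF3-HexCytBR3	NCAAATRTCNTTHTGRGG	YCAYTCDGGYTKRATRTG	373
HexND1F4-HexND1R4	ATHARYTTATCRTANCGR	NTTYGAYTTTKCDGARGG	210
HexND4F4-HexND4R4	HGGDGCYTCNACATGDGC	RGGNTAYCARCCDGARCG	211
HexND5F3-HexND5R3	RTCYYTNGARTAAAAHCC	NGCHAAYTWTGARTWTGA	271
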