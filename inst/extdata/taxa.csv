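taxon_id,genus,label,is_key
AlotL1,Alpheus,A. lottini L1,TRUE
AlotL2,Alpheus,A. lottini L2,TRUE
Alot,Alpheus,A. lottini unresolved,FALSE
Tgut,Trapezia,T. guttata,TRUE
Tsept,Trapezia,T. septata,TRUE
Tspe,Trapezia,T. speciosa,TRUE
Tser,Trapezia,T. serenei,FALSE
Tbel,Trapezia,T. bella,FALSE
Tcymo,Trapezia,T. cymodoce,FALSE
TlutL1,Trapezia,T. lutea L1,FALSE
TlutL2,Trapezia,T. lutea L2,FALSE
TbidL1,Trapezia,T. bidentata L1,FALSE
TbidL2,Trapezia,T. bidentata L2,FALSE
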