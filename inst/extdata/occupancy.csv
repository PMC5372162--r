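colony_id,taxon_id,count
RI-LI-A-b-01,Tgut,1
RI-LI-A-b-02,Tgut,1
RI-LI-A-b-03,Tgut,1
RI-LI-A-b-04,Tgut,1
RI-LI-A-b-05,Tgut,1
RI-LI-A-b-06,Tgut,1
RI-LI-A-b-07,Tgut,1
RI-LI-A-b-08,AlotL1,1
RI-LI-A-b-08,Tgut,1
RI-LI-A-b-09,AlotL1,1
RI-LI-A-b-09,Tgut,1
RI-LI-A-b-10,AlotL1,1
RI-LI-A-b-10,Tgut,1
RI-LI-A-b-11,AlotL1,1
RI-LI-A-b-11,Tgut,1
RI-LI-A-b-12,AlotL1,1
RI-LI-A-b-12,Tgut,1
RI-LI-A-b-13,AlotL1,1
RI-LI-A-b-13,Tgut,1
RI-LI-A-b-14,AlotL1,1
RI-LI-A-b-14,Tgut,1
RI-LI-A-b-15,AlotL1,1
RI-LI-A-b-15,Tgut,1
RI-LI-A-b-16,AlotL1,1
RI-LI-A-b-16,Tgut,1
RI-LI-A-b-17,AlotL1,1
RI-LI-A-b-17,Tgut,1
RI-LI-A-b-18,AlotL1,1
RI-LI-A-b-18,Tgut,1
RI-LI-A-b-19,AlotL1,1
RI-LI-A-b-19,Tgut,1
RI-LI-A-b-20,AlotL1,1
RI-LI-A-b-20,Tgut,1
RI-LI-A-b-21,AlotL1,1
RI-LI-A-b-21,Tgut,1
RI-LI-A-b-21,Tbel,1
RI-LI-A-b-22,AlotL1,1
RI-LI-A-b-22,Tspe,1
RI-LI-A-b-23,AlotL1,1
RI-LI-A-b-23,Tspe,1
RI-LI-A-b-24,AlotL1,1
RI-LI-A-b-24,Tbel,1
RI-LI-A-b-25,AlotL1,1
RI-LI-A-b-25,Tbel,1
RI-LI-A-b-26,Tbel,1
RI-LI-A-b-27,AlotL1,1
RI-LI-A-b-27,TbidL1,1
RI-LI-A-b-28,AlotL1,1
RI-LI-A-b-28,TlutL1,1
RI-LI-A-b-29,AlotL1,1
RI-LI-J-b-01,Tgut,1
RI-LI-J-b-02,Tgut,1
RI-LI-J-b-03,Tgut,1
RI-LI-J-b-04,Tgut,1
RI-LI-J-b-05,Tgut,1
RI-LI-J-b-06,Tgut,1
RI-LI-J-b-07,Tgut,1
RI-LI-J-b-08,AlotL1,1
RI-LI-J-b-08,Tgut,1
RI-LI-J-b-09,AlotL1,1
RI-LI-J-b-09,Tspe,1
RI-LI-J-b-10,Tspe,1
RI-LI-J-b-11,Tspe,1
RI-LI-J-b-12,Tspe,1
RI-LI-J-b-13,Tspe,1
RI-LI-J-b-14,Tspe,1
RI-LI-J-b-15,Tspe,1
RI-LI-J-b-16,Tspe,1
RI-LI-J-b-17,TlutL1,1
RI-LI-J-b-18,TlutL1,1
RI-HI-A-b-01,AlotL1,1
RI-HI-A-b-01,Tgut,1
RI-HI-A-b-02,AlotL1,1
RI-HI-A-b-02,Tspe,1
RI-HI-A-b-03,Tspe,1
RI-HI-A-b-04,Tspe,1
RI-HI-A-b-05,Tspe,1
RI-HI-A-b-06,Tspe,1
RI-HI-A-b-07,Tspe,1
RI-HI-A-b-08,Tspe,1
RI-HI-A-b-09,Tspe,1
RI-HI-A-b-10,Tspe,1
RI-HI-A-b-11,Tspe,1
RI-HI-A-b-12,Tspe,1
RI-HI-A-b-13,Tspe,1
RI-HI-A-b-14,Tspe,1
RI-HI-A-b-15,Tspe,1
RI-HI-A-b-16,Tspe,1
RI-HI-A-b-17,Tspe,1
RI-HI-A-b-18,Tspe,1
RI-HI-A-b-19,Tspe,1
RI-HI-A-b-20,Tspe,1
RI-HI-A-b-21,Tspe,1
RI-HI-A-b-22,Tspe,1
RI-HI-A-b-23,Tspe,1
RI-HI-A-b-24,Tspe,1
RI-HI-A-b-25,Tspe,1
RI-HI-A-b-26,Tspe,1
RI-HI-A-b-26,Tser,1
RI-HI-A-b-26,TbidL1,1
RI-HI-A-b-27,Tbel,1
RI-HI-A-b-28,Tbel,1
RI-HI-A-b-29,AlotL1,1
RI-HI-A-b-29,TlutL1,1
RI-HI-A-b-30,TlutL1,1
RI-HI-J-b-01,Tgut,1
RI-HI-J-b-02,Tgut,1
RI-HI-J-b-03,Tgut,1
RI-HI-J-b-03,Tspe,1
RI-HI-J-b-04,Tspe,1
RI-HI-J-b-05,Tspe,1
RI-HI-J-b-06,Tspe,1
RI-HI-J-b-07,Tspe,1
RI-HI-J-b-08,Tspe,1
RI-HI-J-b-09,Tspe,1
RI-HI-J-b-10,Tspe,1
RI-HI-J-b-11,Tspe,1
RI-HI-J-b-12,Tspe,1
RI-HI-J-b-13,Tspe,1
RI-HI-J-b-14,Tspe,1
RI-HI-J-b-15,Tspe,1
RI-HI-J-b-16,Tspe,1
RI-HI-J-b-17,Tspe,1
RI-HI-J-b-18,Tspe,1
RI-HI-J-b-19,TlutL1,1
NC-LI-A-a-01,AlotL1,1
NC-LI-A-a-01,Tsept,1
NC-LI-A-a-02,AlotL1,1
NC-LI-A-a-02,Tsept,1
NC-LI-A-a-03,AlotL1,1
NC-LI-A-a-03,Tsept,1
NC-LI-A-a-04,AlotL1,1
NC-LI-A-a-04,Tsept,1
NC-LI-A-a-05,AlotL1,1
NC-LI-A-a-05,Tsept,1
NC-LI-A-a-06,AlotL1,1
NC-LI-A-a-06,Tsept,1
NC-LI-A-a-07,AlotL1,1
NC-LI-A-a-07,Tsept,1
NC-LI-A-a-08,AlotL1,1
NC-LI-A-a-08,Tsept,1
NC-LI-A-a-09,AlotL1,1
NC-LI-A-a-09,Tsept,1
NC-LI-A-a-09,Tser,1
NC-LI-A-a-10,AlotL1,1
NC-LI-A-a-10,Alot,1
NC-LI-A-a-10,Tsept,1
NC-LI-A-a-10,Tser,1
NC-LI-A-a-11,AlotL1,1
NC-LI-A-a-11,Tsept,1
NC-LI-A-a-11,TlutL2,1
NC-LI-A-a-12,AlotL2,1
NC-LI-A-a-12,Tsept,1
NC-LI-A-a-13,AlotL2,1
NC-LI-A-a-13,Tsept,1
NC-LI-A-a-14,AlotL2,1
NC-LI-A-a-14,Tsept,1
NC-LI-A-a-15,AlotL2,1
NC-LI-A-a-15,Tsept,1
NC-LI-A-a-16,AlotL2,1
NC-LI-A-a-16,Tsept,1
NC-LI-A-a-17,AlotL2,1
NC-LI-A-a-17,Tsept,1
NC-LI-A-a-18,AlotL2,1
NC-LI-A-a-18,Tsept,1
NC-LI-A-a-18,Tcymo,1
NC-LI-A-a-19,AlotL2,1
NC-LI-A-a-19,Tsept,1
NC-LI-A-a-19,Tcymo,1
NC-LI-A-a-20,AlotL2,1
NC-LI-A-a-20,Tgut,1
NC-LI-A-a-20,Tsept,1
NC-LI-A-a-21,AlotL2,1
NC-LI-A-a-21,Tgut,1
NC-LI-A-a-21,Tsept,1
NC-LI-A-a-22,AlotL1,1
NC-LI-A-a-22,Tgut,1
NC-LI-A-a-23,AlotL2,1
NC-LI-A-a-23,Tcymo,1
NC-LI-A-a-24,AlotL2,1
NC-LI-A-a-24,Tcymo,1
NC-LI-A-a-25,AlotL2,1
NC-LI-A-a-25,Tcymo,1
NC-LI-A-a-25,TlutL2,1
NC-LI-A-a-26,AlotL1,1
NC-LI-A-a-26,AlotL2,1
NC-LI-A-a-26,Tcymo,1
NC-LI-A-a-27,AlotL1,1
NC-LI-A-a-27,Tcymo,1
NC-LI-A-a-27,TlutL2,1
NC-LI-A-a-28,AlotL1,1
NC-LI-A-a-28,TlutL2,1
NC-LI-A-a-29,AlotL1,1
NC-LI-A-a-29,TbidL2,1
NC-LI-A-b-01,AlotL2,1
NC-LI-A-b-01,Tgut,1
NC-LI-J-a-01,AlotL1,1
NC-LI-J-a-01,Tsept,1
NC-LI-J-a-02,Tsept,1
NC-LI-J-a-03,Tsept,1
NC-LI-J-a-04,Tsept,1
NC-LI-J-a-05,Tsept,1
NC-LI-J-a-06,Tsept,1
NC-LI-J-a-07,Tgut,1
NC-LI-J-a-08,Tgut,1
NC-LI-J-a-09,Tgut,1
NC-LI-J-a-10,Tgut,1
NC-LI-J-a-11,Tgut,1
NC-LI-J-a-12,Tgut,1
NC-LI-J-a-13,Tgut,1
NC-LI-J-a-14,Tgut,1
NC-LI-J-a-15,Tgut,1
NC-LI-J-a-16,Tgut,1
NC-LI-J-a-17,Tgut,1
NC-LI-J-a-18,Tgut,1
NC-LI-J-a-19,Tgut,1
NC-LI-J-a-20,Tgut,1
NC-LI-J-a-21,Tcymo,1
NC-LI-J-a-22,Tcymo,1
NC-LI-J-a-23,AlotL2,1
NC-HI-A-a-01,AlotL1,1
NC-HI-A-a-01,Tsept,1
NC-HI-A-a-02,AlotL1,1
NC-HI-A-a-02,Tsept,1
NC-HI-A-a-03,AlotL2,1
NC-HI-A-a-03,Tsept,1
NC-HI-A-a-04,AlotL2,1
NC-HI-A-a-04,Tsept,1
NC-HI-A-a-05,AlotL2,1
NC-HI-A-a-05,Tsept,1
NC-HI-A-a-06,AlotL2,1
NC-HI-A-a-06,Tsept,1
NC-HI-A-a-07,AlotL2,1
NC-HI-A-a-07,Tsept,1
NC-HI-A-a-08,AlotL2,1
NC-HI-A-a-08,Tsept,1
NC-HI-A-a-08,Tser,1
NC-HI-A-a-09,Tsept,1
NC-HI-A-a-10,Tsept,1
NC-HI-A-a-11,Tsept,1
NC-HI-A-a-12,AlotL1,1
NC-HI-A-a-12,Tgut,1
NC-HI-A-a-13,AlotL1,1
NC-HI-A-a-13,Tgut,1
NC-HI-A-a-14,AlotL1,1
NC-HI-A-a-14,Tgut,1
NC-HI-A-a-15,AlotL2,1
NC-HI-A-a-15,Tgut,1
NC-HI-A-a-16,AlotL2,1
NC-HI-A-a-16,Tgut,1
NC-HI-A-a-17,AlotL1,1
NC-HI-A-a-17,TlutL2,1
NC-HI-A-a-18,AlotL2,1
NC-HI-A-a-18,TbidL2,1
NC-HI-A-a-19,AlotL2,1
NC-HI-A-a-19,Tser,1
NC-HI-A-b-01,AlotL1,1
NC-HI-A-b-01,Tsept,1
NC-HI-A-b-02,AlotL1,1
NC-HI-A-b-02,Tsept,1
NC-HI-A-b-03,AlotL1,1
NC-HI-A-b-03,Tsept,1
NC-HI-A-b-04,AlotL1,1
NC-HI-A-b-04,Tsept,1
NC-HI-A-b-05,AlotL2,1
NC-HI-A-b-05,Tsept,1
NC-HI-A-b-06,AlotL2,1
NC-HI-A-b-06,Tsept,1
NC-HI-A-b-07,Tgut,1
NC-HI-A-b-08,Tgut,1
NC-HI-A-b-09,AlotL2,1
NC-HI-A-b-09,TlutL2,1
NC-HI-A-b-10,TlutL2,1
NC-HI-J-a-01,Tgut,1
NC-HI-J-b-01,Tgut,1
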