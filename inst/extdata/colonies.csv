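colony_id,region,site,stage,host_type,L_cm,l_cm
RI-LI-A-b-01,RI,LI,adult,beta,,
RI-LI-A-b-02,RI,LI,adult,beta,,
RI-LI-A-b-03,RI,LI,adult,beta,,
RI-LI-A-b-04,RI,LI,adult,beta,,
RI-LI-A-b-05,RI,LI,adult,beta,,
RI-LI-A-b-06,RI,LI,adult,beta,,
RI-LI-A-b-07,RI,LI,adult,beta,,
RI-LI-A-b-08,RI,LI,adult,beta,,
RI-LI-A-b-09,RI,LI,adult,beta,,
RI-LI-A-b-10,RI,LI,adult,beta,,
RI-LI-A-b-11,RI,LI,adult,beta,,
RI-LI-A-b-12,RI,LI,adult,beta,,
RI-LI-A-b-13,RI,LI,adult,beta,,
RI-LI-A-b-14,RI,LI,adult,beta,,
RI-LI-A-b-15,RI,LI,adult,beta,,
RI-LI-A-b-16,RI,LI,adult,beta,,
RI-LI-A-b-17,RI,LI,adult,beta,,
RI-LI-A-b-18,RI,LI,adult,beta,,
RI-LI-A-b-19,RI,LI,adult,beta,,
RI-LI-A-b-20,RI,LI,adult,beta,,
RI-LI-A-b-21,RI,LI,adult,beta,,
RI-LI-A-b-22,RI,LI,adult,beta,,
RI-LI-A-b-23,RI,LI,adult,beta,,
RI-LI-A-b-24,RI,LI,adult,beta,,
RI-LI-A-b-25,RI,LI,adult,beta,,
RI-LI-A-b-26,RI,LI,adult,beta,,
RI-LI-A-b-27,RI,LI,adult,beta,,
RI-LI-A-b-28,RI,LI,adult,beta,,
RI-LI-A-b-29,RI,LI,adult,beta,,
RI-LI-A-b-30,RI,LI,adult,beta,,
RI-LI-J-b-01,RI,LI,juvenile,beta,,
RI-LI-J-b-02,RI,LI,juvenile,beta,,
RI-LI-J-b-03,RI,LI,juvenile,beta,,
RI-LI-J-b-04,RI,LI,juvenile,beta,,
RI-LI-J-b-05,RI,LI,juvenile,beta,,
RI-LI-J-b-06,RI,LI,juvenile,beta,,
RI-LI-J-b-07,RI,LI,juvenile,beta,,
RI-LI-J-b-08,RI,LI,juvenile,beta,,
RI-LI-J-b-09,RI,LI,juvenile,beta,,
RI-LI-J-b-10,RI,LI,juvenile,beta,,
RI-LI-J-b-11,RI,LI,juvenile,beta,,
RI-LI-J-b-12,RI,LI,juvenile,beta,,
RI-LI-J-b-13,RI,LI,juvenile,beta,,
RI-LI-J-b-14,RI,LI,juvenile,beta,,
RI-LI-J-b-15,RI,LI,juvenile,beta,,
RI-LI-J-b-16,RI,LI,juvenile,beta,,
RI-LI-J-b-17,RI,LI,juvenile,beta,,
RI-LI-J-b-18,RI,LI,juvenile,beta,,
RI-LI-J-b-19,RI,LI,juvenile,beta,,
RI-LI-J-b-20,RI,LI,juvenile,beta,,
RI-LI-J-b-21,RI,LI,juvenile,beta,,
RI-LI-J-b-22,RI,LI,juvenile,beta,,
RI-LI-J-b-23,RI,LI,juvenile,beta,,
RI-LI-J-b-24,RI,LI,juvenile,beta,,
RI-LI-J-b-25,RI,LI,juvenile,beta,,
RI-LI-J-b-26,RI,LI,juvenile,beta,,
RI-LI-J-b-27,RI,LI,juvenile,beta,,
RI-LI-J-b-28,RI,LI,juvenile,beta,,
RI-LI-J-b-29,RI,LI,juvenile,beta,,
RI-LI-J-b-30,RI,LI,juvenile,beta,,
RI-LI-J-b-31,RI,LI,juvenile,beta,,
RI-HI-A-b-01,RI,HI,adult,beta,,
RI-HI-A-b-02,RI,HI,adult,beta,,
RI-HI-A-b-03,RI,HI,adult,beta,,
RI-HI-A-b-04,RI,HI,adult,beta,,
RI-HI-A-b-05,RI,HI,adult,beta,,
RI-HI-A-b-06,RI,HI,adult,beta,,
RI-HI-A-b-07,RI,HI,adult,beta,,
RI-HI-A-b-08,RI,HI,adult,beta,,
RI-HI-A-b-09,RI,HI,adult,beta,,
RI-HI-A-b-10,RI,HI,adult,beta,,
RI-HI-A-b-11,RI,HI,adult,beta,,
RI-HI-A-b-12,RI,HI,adult,beta,,
RI-HI-A-b-13,RI,HI,adult,beta,,
RI-HI-A-b-14,RI,HI,adult,beta,,
RI-HI-A-b-15,RI,HI,adult,beta,,
RI-HI-A-b-16,RI,HI,adult,beta,,
RI-HI-A-b-17,RI,HI,adult,beta,,
RI-HI-A-b-18,RI,HI,adult,beta,,
RI-HI-A-b-19,RI,HI,adult,beta,,
RI-HI-A-b-20,RI,HI,adult,beta,,
RI-HI-A-b-21,RI,HI,adult,beta,,
RI-HI-A-b-22,RI,HI,adult,beta,,
RI-HI-A-b-23,RI,HI,adult,beta,,
RI-HI-A-b-24,RI,HI,adult,beta,,
RI-HI-A-b-25,RI,HI,adult,beta,,
RI-HI-A-b-26,RI,HI,adult,beta,,
RI-HI-A-b-27,RI,HI,adult,beta,,
RI-HI-A-b-28,RI,HI,adult,beta,,
RI-HI-A-b-29,RI,HI,adult,beta,,
RI-HI-A-b-30,RI,HI,adult,beta,,
RI-HI-A-b-31,RI,HI,adult,beta,,
RI-HI-J-b-01,RI,HI,juvenile,beta,,
RI-HI-J-b-02,RI,HI,juvenile,beta,,
RI-HI-J-b-03,RI,HI,juvenile,beta,,
RI-HI-J-b-04,RI,HI,juvenile,beta,,
RI-HI-J-b-05,RI,HI,juvenile,beta,,
RI-HI-J-b-06,RI,HI,juvenile,beta,,
RI-HI-J-b-07,RI,HI,juvenile,beta,,
RI-HI-J-b-08,RI,HI,juvenile,beta,,
RI-HI-J-b-09,RI,HI,juvenile,beta,,
RI-HI-J-b-10,RI,HI,juvenile,beta,,
RI-HI-J-b-11,RI,HI,juvenile,beta,,
RI-HI-J-b-12,RI,HI,juvenile,beta,,
RI-HI-J-b-13,RI,HI,juvenile,beta,,
RI-HI-J-b-14,RI,HI,juvenile,beta,,
RI-HI-J-b-15,RI,HI,juvenile,beta,,
RI-HI-J-b-16,RI,HI,juvenile,beta,,
RI-HI-J-b-17,RI,HI,juvenile,beta,,
RI-HI-J-b-18,RI,HI,juvenile,beta,,
RI-HI-J-b-19,RI,HI,juvenile,beta,,
RI-HI-J-b-20,RI,HI,juvenile,beta,,
RI-HI-J-b-21,RI,HI,juvenile,beta,,
RI-HI-J-b-22,RI,HI,juvenile,beta,,
RI-HI-J-b-23,RI,HI,juvenile,beta,,
RI-HI-J-b-24,RI,HI,juvenile,beta,,
RI-HI-J-b-25,RI,HI,juvenile,beta,,
NC-LI-A-a-01,NC,LI,adult,alpha,,
NC-LI-A-a-02,NC,LI,adult,alpha,,
NC-LI-A-a-03,NC,LI,adult,alpha,,
NC-LI-A-a-04,NC,LI,adult,alpha,,
NC-LI-A-a-05,NC,LI,adult,alpha,,
NC-LI-A-a-06,NC,LI,adult,alpha,,
NC-LI-A-a-07,NC,LI,adult,alpha,,
NC-LI-A-a-08,NC,LI,adult,alpha,,
NC-LI-A-a-09,NC,LI,adult,alpha,,
NC-LI-A-a-10,NC,LI,adult,alpha,,
NC-LI-A-a-11,NC,LI,adult,alpha,,
NC-LI-A-a-12,NC,LI,adult,alpha,,
NC-LI-A-a-13,NC,LI,adult,alpha,,
NC-LI-A-a-14,NC,LI,adult,alpha,,
NC-LI-A-a-15,NC,LI,adult,alpha,,
NC-LI-A-a-16,NC,LI,adult,alpha,,
NC-LI-A-a-17,NC,LI,adult,alpha,,
NC-LI-A-a-18,NC,LI,adult,alpha,,
NC-LI-A-a-19,NC,LI,adult,alpha,,
NC-LI-A-a-20,NC,LI,adult,alpha,,
NC-LI-A-a-21,NC,LI,adult,alpha,,
NC-LI-A-a-22,NC,LI,adult,alpha,,
NC-LI-A-a-23,NC,LI,adult,alpha,,
NC-LI-A-a-24,NC,LI,adult,alpha,,
NC-LI-A-a-25,NC,LI,adult,alpha,,
NC-LI-A-a-26,NC,LI,adult,alpha,,
NC-LI-A-a-27,NC,LI,adult,alpha,,
NC-LI-A-a-28,NC,LI,adult,alpha,,
NC-LI-A-a-29,NC,LI,adult,alpha,,
NC-LI-A-b-01,NC,LI,adult,beta,,
NC-LI-J-a-01,NC,LI,juvenile,alpha,,
NC-LI-J-a-02,NC,LI,juvenile,alpha,,
NC-LI-J-a-03,NC,LI,juvenile,alpha,,
NC-LI-J-a-04,NC,LI,juvenile,alpha,,
NC-LI-J-a-05,NC,LI,juvenile,alpha,,
NC-LI-J-a-06,NC,LI,juvenile,alpha,,
NC-LI-J-a-07,NC,LI,juvenile,alpha,,
NC-LI-J-a-08,NC,LI,juvenile,alpha,,
NC-LI-J-a-09,NC,LI,juvenile,alpha,,
NC-LI-J-a-10,NC,LI,juvenile,alpha,,
NC-LI-J-a-11,NC,LI,juvenile,alpha,,
NC-LI-J-a-12,NC,LI,juvenile,alpha,,
NC-LI-J-a-13,NC,LI,juvenile,alpha,,
NC-LI-J-a-14,NC,LI,juvenile,alpha,,
NC-LI-J-a-15,NC,LI,juvenile,alpha,,
NC-LI-J-a-16,NC,LI,juvenile,alpha,,
NC-LI-J-a-17,NC,LI,juvenile,alpha,,
NC-LI-J-a-18,NC,LI,juvenile,alpha,,
NC-LI-J-a-19,NC,LI,juvenile,alpha,,
NC-LI-J-a-20,NC,LI,juvenile,alpha,,
NC-LI-J-a-21,NC,LI,juvenile,alpha,,
NC-LI-J-a-22,NC,LI,juvenile,alpha,,
NC-LI-J-a-23,NC,LI,juvenile,alpha,,
NC-LI-J-a-24,NC,LI,juvenile,alpha,,
NC-LI-J-a-25,NC,LI,juvenile,alpha,,
NC-LI-J-a-26,NC,LI,juvenile,alpha,,
NC-LI-J-a-27,NC,LI,juvenile,alpha,,
NC-LI-J-a-28,NC,LI,juvenile,alpha,,
NC-LI-J-a-29,NC,LI,juvenile,alpha,,
NC-LI-J-a-30,NC,LI,juvenile,alpha,,
NC-HI-A-a-01,NC,HI,adult,alpha,,
NC-HI-A-a-02,NC,HI,adult,alpha,,
NC-HI-A-a-03,NC,HI,adult,alpha,,
NC-HI-A-a-04,NC,HI,adult,alpha,,
NC-HI-A-a-05,NC,HI,adult,alpha,,
NC-HI-A-a-06,NC,HI,adult,alpha,,
NC-HI-A-a-07,NC,HI,adult,alpha,,
NC-HI-A-a-08,NC,HI,adult,alpha,,
NC-HI-A-a-09,NC,HI,adult,alpha,,
NC-HI-A-a-10,NC,HI,adult,alpha,,
NC-HI-A-a-11,NC,HI,adult,alpha,,
NC-HI-A-a-12,NC,HI,adult,alpha,,
NC-HI-A-a-13,NC,HI,adult,alpha,,
NC-HI-A-a-14,NC,HI,adult,alpha,,
NC-HI-A-a-15,NC,HI,adult,alpha,,
NC-HI-A-a-16,NC,HI,adult,alpha,,
NC-HI-A-a-17,NC,HI,adult,alpha,,
NC-HI-A-a-18,NC,HI,adult,alpha,,
NC-HI-A-a-19,NC,HI,adult,alpha,,
NC-HI-A-b-01,NC,HI,adult,beta,,
NC-HI-A-b-02,NC,HI,adult,beta,,
NC-HI-A-b-03,NC,HI,adult,beta,,
NC-HI-A-b-04,NC,HI,adult,beta,,
NC-HI-A-b-05,NC,HI,adult,beta,,
NC-HI-A-b-06,NC,HI,adult,beta,,
NC-HI-A-b-07,NC,HI,adult,beta,,
NC-HI-A-b-08,NC,HI,adult,beta,,
NC-HI-A-b-09,NC,HI,adult,beta,,
NC-HI-A-b-10,NC,HI,adult,beta,,
NC-HI-J-a-01,NC,HI,juvenile,alpha,,
NC-HI-J-a-02,NC,HI,juvenile,alpha,,
NC-HI-J-a-03,NC,HI,juvenile,alpha,,
NC-HI-J-a-04,NC,HI,juvenile,alpha,,
NC-HI-J-a-05,NC,HI,juvenile,alpha,,
NC-HI-J-a-06,NC,HI,juvenile,alpha,,
NC-HI-J-a-07,NC,HI,juvenile,alpha,,
NC-HI-J-a-08,NC,HI,juvenile,alpha,,
NC-HI-J-a-09,NC,HI,juvenile,alpha,,
NC-HI-J-a-10,NC,HI,juvenile,alpha,,
NC-HI-J-b-01,NC,HI,juvenile,beta,,
NC-HI-J-b-02,NC,HI,juvenile,beta,,
NC-HI-J-b-03,NC,HI,juvenile,beta,,
NC-HI-J-b-04,NC,HI,juvenile,beta,,
NC-HI-J-b-05,NC,HI,juvenile,beta,,
NC-HI-J-b-06,NC,HI,juvenile,beta,,
NC-HI-J-b-07,NC,HI,juvenile,beta,,
NC-HI-J-b-08,NC,HI,juvenile,beta,,
NC-HI-J-b-09,NC,HI,juvenile,beta,,
NC-HI-J-b-10,NC,HI,juvenile,beta,,
NC-HI-J-b-11,NC,HI,juvenile,beta,,
NC-HI-J-b-12,NC,HI,juvenile,beta,,
NC-HI-J-b-13,NC,HI,juvenile,beta,,
NC-HI-J-b-14,NC,HI,juvenile,beta,,
NC-HI-J-b-15,NC,HI,juvenile,beta,,
NC-HI-J-b-16,NC,HI,juvenile,beta,,
NC-HI-J-b-17,NC,HI,juvenile,beta,,
NC-HI-J-b-18,NC,HI,juvenile,beta,,
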