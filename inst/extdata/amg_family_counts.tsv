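family	count_am54	count_am48
amg-miR159	3158	1008
amg-miR156	5340	1559
amg-miR166	1578	464
amg-miR164	5444	5371
amg-miR168	78825	33365
amg-miR172	32449	18189
amg-miR394	2037	226
amg-miR396	638	288
amg-miR160	29	32
amg-miR167	267	325
amg-miR162	990	175
amg-miR403	34	20
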