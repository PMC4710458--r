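variable,ENS,DFA,RF,MARS,MANN
Mean segment elevation,1,6,1,1,1
Catchment average slope,3,3,3,2,6
Distance to outlet (the sea),6,7,2,,3
Mean annual runoff,2,5,9,,2
Catchment shape (elongation ratio),5,4,7,,4
Maximum upstream elevation,4,,4,,12
Stream and sub-catchment average annual rainfall,7,,8,,5
Stream and sub-catchment hottest month mean temperature,12,1,6,,9
Average slope of downstream flow path,9,,10,,7
Catchment relief ratio,8,,5,,13
Catchment percentage unconsolidated rocks,16,2,14,,10
Catchment percentage igneous rocks,10,,13,,14
Modelled annual terrestrial mean net primary productivity,17,,12,,8
Coefficient of variation of monthly totals of accumulated soil water surplus,11,,11,,17
Stream and valley percentage siliciclastic/undifferentiated sedimentary rocks,13,,15,,11
Stream and valley percentage unconsolidated rocks,15,,16,,15
Catchment percentage metamorphic rocks,14,,17,,19
Stream and valley percentage metamorphic rocks,18,,19,,18
Stream and valley percentage mixed sedimentary and igneous rocks,20,,20,,16
Catchment percentage mixed sedimentary and igneous rocks,19,,18,,20
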