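key,description
0,unused placeholder bit
1,isotope
2,atomic number 104 or greater
3,heavy group 14-16 element (Ge As Se Sn Sb Te Pb Bi Po)
4,actinide
5,group 3B or 4B transition metal (Sc Ti Y Zr Hf)
6,lanthanide
7,group 5B-7B transition metal (V Cr Mn Nb Mo Tc Ta W Re)
8,heteroatom in a four-membered ring
9,group 8-10 transition metal (Fe Co Ni Ru Rh Pd Os Ir Pt)
10,alkaline earth metal
11,four-membered ring
12,group 11 or 12 metal (Cu Zn Ag Cd Au Hg)
13,oxygen on a nitrogen bearing two carbons
14,sulfur-sulfur bond
15,carbon bonded to three oxygens
16,heteroatom in a three-membered ring
17,carbon-carbon triple bond
18,group 13 element (B Al Ga In Tl)
19,seven-membered ring
20,silicon
21,alkene carbon bearing two heteroatoms
22,three-membered ring
23,nitrogen on a carbon bearing two oxygens
24,nitrogen-oxygen single bond
25,nitrogen on a carbon bearing two nitrogens (guanidine-like)
26,ring carbon-carbon double bond with ring substituents
27,iodine
28,heteroatoms on both sides of a methylene bridge
29,phosphorus
30,carbon on a heteroatom bearing three further neighbours
31,heteroatom-halogen bond
32,carbon-sulfur-nitrogen path
33,nitrogen-sulfur bond
34,terminal methylene (CH2 double-bonded)
35,alkali metal
36,sulfur in a ring
37,urea-like nitrogen-carbonyl-nitrogen motif
38,amidine-like nitrogen-carbon-nitrogen motif
39,sulfur-like heteroatom path with three oxygens on sulfur (sulfonate-like)
40,sulfur-oxygen single bond
41,nitrile group (carbon-nitrogen triple bond)
42,fluorine
43,two hydrogen-bearing heteroatoms separated by one atom
44,unusual element (outside C N O F Si P S Cl Br I)
45,alkene carbon attached to nitrogen
46,bromine
47,sulfur and nitrogen separated by one atom
48,heteroatom bonded to three oxygen atoms
49,formally charged atom
50,trisubstituted alkene carbon
51,carbon-sulfur-oxygen path
52,nitrogen-nitrogen bond
53,two hydrogen-bearing heteroatoms separated by three atoms
54,two hydrogen-bearing heteroatoms separated by two atoms
55,sulfur bearing two oxygens (sulfonyl-like)
56,nitro-like oxygen-nitrogen(oxygen)-carbon motif
57,oxygen in a ring
58,heteroatom-sulfur-heteroatom path
59,sulfur attached to an aromatic ring by a non-aromatic bond
60,sulfur-oxygen double bond
61,sulfur with three neighbours
62,ring atoms joined through a non-ring bond
63,nitrogen-oxygen double bond
64,ring atom with an exocyclic sulfur
65,aromatic carbon-nitrogen bond
66,carbon bearing three carbons and a further neighbour
67,heteroatom attached to sulfur
68,two adjacent hydrogen-bearing heteroatoms
69,heteroatom adjacent to a hydrogen-bearing heteroatom
70,nitrogen flanked by two heteroatoms
71,nitrogen-oxygen bond
72,two oxygens separated by two atoms
73,sulfur double bond
74,two methyl groups separated by one atom
75,ring nitrogen with an acyclic substituent
76,disubstituted alkene carbon
77,two nitrogens separated by one atom
78,carbon-nitrogen double bond (imine-like)
79,two nitrogens separated by two atoms
80,two nitrogens separated by three atoms
81,branched sulfur with three neighbours
82,methylene adjacent to a hydrogen-bearing heteroatom
83,heteroatom in a five-membered ring
84,primary amine (NH2)
85,tertiary amine (nitrogen bonded to three carbons)
86,two small alkyl carbons bridged by a heteroatom
87,halogen one bond away from a ring
88,sulfur
89,two oxygens separated by three atoms
90,hydrogen-bearing heteroatom two atoms from a methylene
91,hydrogen-bearing heteroatom three atoms from a methylene
92,amide-like oxygen-carbon(nitrogen)-carbon motif
93,methyl attached to a heteroatom
94,nitrogen attached to a heteroatom
95,nitrogen and oxygen separated by two atoms
96,five-membered ring
97,nitrogen and oxygen separated by three atoms
98,heteroatom in a six-membered ring
99,carbon-carbon double bond
100,methylene attached to nitrogen
101,ring of eight or more members
102,heteroatom attached to oxygen
103,chlorine
104,hydrogen-bearing heteroatom one atom from a methylene
105,atom with three ring bonds (ring fusion atom)
106,heteroatom bonded to three heteroatoms
107,halogen on a branched atom
108,methyl three atoms from a methylene
109,methylene attached to oxygen
110,nitrogen-carbon-oxygen path
111,nitrogen one atom from a methylene
112,atom with four or more neighbours
113,oxygen attached to an aromatic ring by a non-aromatic bond
114,ethyl group
115,methyl one atom from a methylene
116,methyl two atoms from a methylene
117,nitrogen and oxygen separated by one atom
118,more than one ethylene-like CH2-CH2 bridge
119,nitrogen double bond
120,more than one heteroatom in rings
121,nitrogen in a ring
122,nitrogen with three neighbours
123,acetal-like oxygen-carbon-oxygen motif
124,two heteroatoms bonded to each other
125,more than one aromatic ring
126,oxygen in an acyclic bridge between two atoms (ether-like)
127,more than one ring atom with an exocyclic oxygen
128,two methylenes separated by three atoms
129,two methylenes separated by two atoms
130,more than one heteroatom-heteroatom bond
131,more than one hydrogen-bearing heteroatom
132,oxygen one atom from a methylene
133,ring atom with an exocyclic nitrogen
134,halogen
135,nitrogen attached to an aromatic ring by a non-aromatic bond
136,more than one double-bonded oxygen
137,non-carbon atom in a ring (heterocycle)
138,more than one methylene attached to a heteroatom
139,hydroxyl-like oxygen bearing hydrogen
140,four or more oxygens
141,three or more methyl groups
142,two or more nitrogens
143,ring atom with an exocyclic oxygen
144,atom at an aromatic/non-aromatic boundary
145,two or more six-membered rings
146,three or more oxygens
147,ethylene-like CH2-CH2 bridge
148,heteroatom with three neighbours
149,two or more methyl groups
150,acyclic bond linking two ring systems
151,nitrogen bearing hydrogen (NH)
152,ketone-like oxygen-carbon(carbon)-carbon motif
153,heteroatom attached to a methylene
154,carbonyl group (carbon-oxygen double bond)
155,acyclic methylene bridge
156,branched nitrogen with three neighbours
157,carbon-oxygen single bond
158,carbon-nitrogen single bond
159,two or more oxygens
160,methyl group
161,nitrogen
162,aromatic atom
163,six-membered ring
164,oxygen
165,ring
166,more than one molecular fragment
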