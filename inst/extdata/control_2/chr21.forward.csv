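pos,c,noc,mc,hmc
1,50,1,6,0
2,38,0,6,0
3,56,1,1,0
4,28,0,24,0
5,53,0,0,0
6,60,0,3,0
7,39,0,5,0
8,35,1,27,0
9,38,2,11,0
10,45,0,3,0
11,51,0,2,0
12,40,1,8,0
13,47,0,4,0
14,51,0,1,0
15,29,0,14,0
16,34,1,4,0
17,46,2,8,0
18,40,1,20,0
19,59,2,0,0
20,47,0,0,0
21,43,2,4,0
22,45,1,13,0
23,47,1,10,0
24,34,0,7,0
26,53,0,0,0
27,64,1,1,0
28,46,0,2,0
29,65,1,0,0
30,53,0,2,0
31,64,1,4,0
32,41,1,2,0
33,48,0,0,0
34,44,1,3,0
35,50,0,1,0
36,40,0,4,0
37,44,1,0,0
38,50,1,2,0
39,48,0,1,0
40,35,0,5,0
42,43,0,11,0
43,39,0,0,0
44,38,0,2,0
46,30,0,12,0
48,61,0,3,0
49,47,1,7,0
50,50,0,1,0
51,37,0,14,0
52,42,0,1,0
54,46,0,0,0
55,43,0,8,0
56,46,0,1,0
57,22,0,15,0
58,46,0,2,0
59,41,1,11,0
60,52,0,0,0
61,26,1,31,0
62,52,0,2,0
63,45,1,5,0
64,43,0,4,0
65,51,2,3,0
66,32,0,19,0
67,41,0,2,0
68,49,0,0,0
69,54,0,2,0
70,42,0,3,0
71,51,1,0,0
72,42,0,0,0
73,48,0,3,0
74,54,1,0,0
75,56,0,0,0
77,44,0,6,0
79,49,2,2,0
81,44,0,2,0
83,51,0,0,0
84,56,0,3,0
86,63,0,2,0
87,56,0,2,0
88,49,1,0,0
89,46,0,1,0
90,54,0,18,0
91,38,0,14,0
92,55,0,2,0
93,35,0,1,0
94,49,1,0,0
95,50,0,2,0
96,52,1,5,0
97,60,1,0,0
98,51,2,0,0
99,52,1,0,0
100,43,0,5,0
101,35,0,0,0
102,34,1,23,0
103,40,0,4,0
104,40,0,2,0
105,59,1,1,0
106,41,0,8,0
107,37,1,3,0
108,41,1,5,0
109,36,2,11,0
110,30,0,5,0
111,47,0,12,0
112,37,0,1,0
113,41,1,4,0
114,59,1,1,0
115,43,0,11,0
116,49,1,1,0
117,32,0,11,0
118,43,0,4,0
119,55,0,0,0
120,48,1,8,0
121,58,3,3,0
122,48,2,9,0
123,44,1,7,0
124,50,1,1,0
125,49,1,11,0
126,42,1,22,0
127,39,0,2,0
128,55,1,3,0
129,43,1,4,0
130,32,1,5,0
131,33,1,16,0
132,37,0,10,0
133,44,0,0,0
134,53,1,1,0
135,39,0,11,0
136,48,0,6,0
137,48,0,8,0
138,40,0,0,0
140,19,1,19,0
141,33,1,15,0
142,58,1,2,0
143,43,1,11,0
144,46,1,2,0
145,42,0,12,0
146,41,1,5,0
148,43,1,6,0
149,43,3,4,0
150,45,1,3,0
151,42,0,5,0
152,34,0,19,0
153,47,0,7,0
154,41,0,0,0
155,44,0,5,0
156,46,1,11,0
158,55,0,5,0
159,40,1,7,0
160,44,0,3,0
161,46,0,3,0
162,43,0,3,0
163,53,1,1,0
164,36,0,6,0
165,34,0,13,0
166,48,0,3,0
167,51,0,10,0
168,43,0,4,0
169,46,0,4,0
170,48,1,13,0
171,50,0,7,0
174,50,0,10,0
175,34,1,9,0
176,29,1,3,0
178,38,0,4,0
179,52,0,1,0
180,46,1,3,0
181,56,0,0,0
182,32,0,6,0
183,41,0,0,0
184,46,0,3,0
185,39,1,5,0
186,32,0,20,0
187,50,0,11,0
189,15,0,39,0
190,42,0,0,0
191,36,0,9,0
192,50,2,4,0
193,19,2,27,0
194,49,0,1,0
195,55,0,1,0
196,37,0,7,0
197,31,1,12,0
199,44,0,11,0
200,44,1,5,0
201,40,0,3,0
203,47,1,0,0
204,39,0,11,0
205,51,2,15,0
206,60,1,3,0
207,53,0,0,0
208,40,0,6,0
210,49,0,7,0
211,32,1,5,0
212,42,2,11,0
213,47,0,0,0
214,51,0,0,0
215,49,0,6,0
216,45,0,0,0
217,52,0,3,0
218,47,1,1,0
219,45,0,2,0
220,43,0,13,0
221,64,1,0,0
222,54,0,1,0
223,60,1,2,0
224,41,0,0,0
225,51,0,8,0
226,20,0,25,0
227,44,0,0,0
228,55,0,1,0
229,53,0,6,0
230,43,0,2,0
232,46,0,0,0
233,45,1,0,0
234,46,1,0,0
236,52,0,4,0
238,42,1,10,0
239,32,1,18,0
240,46,1,5,0
241,43,1,3,0
242,48,0,1,0
243,46,1,1,0
244,56,0,3,0
245,34,0,9,0
246,45,0,4,0
247,43,0,2,0
248,40,0,5,0
249,49,0,2,0
250,54,1,8,0
251,57,0,1,0
253,40,1,0,0
254,49,0,1,0
255,36,0,3,0
256,44,2,1,0
258,32,0,12,0
259,64,1,0,0
260,65,0,0,0
261,53,0,1,0
262,55,1,2,0
263,58,1,0,0
264,46,0,5,0
265,36,0,8,0
266,54,0,7,0
267,50,1,2,0
268,41,0,10,0
269,29,0,2,0
270,39,1,4,0
271,48,0,4,0
272,63,0,0,0
273,43,0,3,0
274,46,1,9,0
275,29,0,21,0
276,48,1,0,0
277,54,0,3,0
278,45,0,15,0
279,39,1,3,0
280,38,0,14,0
281,29,1,13,0
282,37,3,10,0
283,45,0,6,0
284,38,3,6,0
285,35,0,7,0
286,47,0,2,0
287,35,1,10,0
288,28,0,7,0
289,33,0,24,0
290,56,0,1,0
291,38,0,4,0
292,56,3,8,0
293,36,0,2,0
294,36,0,12,0
295,41,1,13,0
296,58,0,0,0
297,28,0,11,0
298,34,1,22,0
299,48,0,2,0
300,40,0,11,0
301,47,0,6,0
302,48,1,3,0
303,49,1,0,0
304,41,1,4,0
305,46,0,16,0
306,42,0,8,0
307,26,0,5,0
308,44,1,0,0
309,37,0,0,0
310,46,0,2,0
311,47,0,3,0
312,45,0,20,0
313,41,0,1,0
314,31,1,4,0
316,65,1,2,0
317,48,0,1,0
319,49,0,1,0
320,38,0,1,0
321,43,0,1,0
322,44,0,4,0
323,38,0,1,0
324,44,0,3,0
325,31,1,12,0
326,51,0,6,0
327,52,0,0,0
328,53,1,3,0
329,47,0,10,0
330,46,1,16,0
331,62,0,3,0
332,43,0,13,0
333,42,1,2,0
334,49,1,3,0
335,45,1,11,0
336,31,0,10,0
337,40,0,7,0
338,55,0,7,0
339,44,2,5,0
340,39,0,5,0
341,49,1,8,0
342,53,0,3,0
343,45,0,2,0
344,40,0,3,0
345,43,0,9,0
347,49,2,1,0
348,33,1,7,0
349,41,0,2,0
350,33,0,3,0
352,50,0,3,0
353,46,0,0,0
354,47,0,1,0
355,43,0,2,0
356,47,1,1,0
358,40,1,7,0
359,46,0,3,0
360,34,0,8,0
361,56,2,1,0
363,58,1,4,0
365,42,0,0,0
366,46,2,9,0
368,43,0,6,0
369,45,1,0,0
370,32,1,6,0
371,41,1,4,0
372,47,0,5,0
373,42,0,1,0
374,44,1,3,0
375,44,1,1,0
377,52,1,2,0
378,47,1,0,0
380,53,0,1,0
381,34,0,11,0
382,41,0,1,0
383,39,1,14,0
384,45,1,4,0
386,46,3,3,0
387,32,0,15,0
388,41,0,1,0
389,54,0,1,0
390,54,0,1,0
391,58,1,1,0
392,44,0,2,0
393,46,0,4,0
394,40,0,0,0
395,26,0,12,0
396,38,0,1,0
397,58,1,0,0
398,32,0,0,0
399,36,0,17,0
400,50,0,2,0
401,47,1,1,0
402,54,0,3,0
403,47,0,0,0
404,50,1,6,0
406,29,2,3,0
407,45,1,5,0
408,54,0,3,0
409,43,1,0,0
410,42,0,4,0
411,45,0,4,0
412,50,1,0,0
414,47,0,3,0
415,47,0,3,0
416,58,2,10,0
417,75,1,0,0
418,54,1,3,0
419,54,0,1,0
420,48,1,1,0
421,45,2,3,0
422,41,1,1,0
423,45,0,0,0
424,50,0,0,0
425,42,1,6,0
426,42,1,1,0
427,46,0,8,0
428,47,0,3,0
429,40,0,1,0
430,51,0,0,0
431,44,2,5,0
432,38,1,1,0
434,37,0,6,0
435,30,0,14,0
436,46,0,6,0
437,50,0,1,0
438,41,1,5,0
439,48,2,0,0
440,42,0,5,0
441,51,0,11,0
442,55,0,3,0
443,43,0,10,0
444,53,0,1,0
445,42,0,4,0
446,51,1,0,0
447,37,1,12,0
448,52,0,0,0
449,53,1,3,0
450,33,0,14,0
451,32,0,10,0
452,53,0,9,0
453,61,0,0,0
454,34,1,9,0
455,43,0,8,0
456,54,2,2,0
457,62,0,2,0
458,42,0,4,0
459,39,1,5,0
460,47,1,0,0
461,41,0,3,0
462,51,0,3,0
463,62,0,0,0
464,50,0,0,0
465,53,0,5,0
466,47,0,0,0
467,34,0,13,0
468,45,1,1,0
469,47,1,3,0
470,58,2,0,0
471,36,0,14,0
472,48,1,1,0
474,45,0,6,0
475,63,0,0,0
476,40,1,4,0
477,47,0,8,0
478,43,0,2,0
479,50,1,0,0
480,44,2,1,0
481,45,1,0,0
482,41,0,1,0
483,42,0,0,0
484,45,1,0,0
485,35,1,10,0
486,41,0,2,0
487,44,0,4,0
488,51,0,2,0
489,23,0,11,0
490,41,1,0,0
491,62,0,1,0
492,50,0,5,0
493,47,4,4,0
495,43,0,7,0
496,49,1,1,0
497,35,0,22,0
498,45,0,9,0
499,53,0,2,0
500,42,0,2,0
501,46,0,12,0
502,47,1,6,0
504,40,0,10,0
505,50,0,0,0
506,41,1,10,0
507,47,1,0,0
508,58,1,0,0
510,61,1,0,0
511,50,0,1,0
512,59,0,0,0
513,58,1,1,0
514,45,0,10,0
515,42,1,5,0
517,57,2,20,0
518,57,1,1,0
519,57,0,0,0
520,47,0,7,0
521,49,0,3,0
522,41,2,6,0
523,50,0,2,0
524,45,0,4,0
525,50,0,1,0
526,52,3,2,0
527,47,0,9,0
528,51,0,1,0
530,36,1,10,0
531,47,0,5,0
532,38,0,3,0
533,36,1,9,0
534,51,1,1,0
535,54,0,6,0
536,48,1,3,0
537,45,0,0,0
538,41,2,9,0
539,39,0,2,0
540,37,0,10,0
541,48,0,4,0
542,43,1,0,0
543,41,1,4,0
544,29,0,5,0
545,53,0,0,0
546,56,3,4,0
547,41,0,3,0
548,39,0,9,0
549,51,0,4,0
550,48,0,5,0
551,39,0,7,0
553,53,2,2,0
554,69,0,2,0
555,41,1,21,0
556,41,1,0,0
558,36,1,4,0
559,48,0,2,0
560,52,1,0,0
561,31,1,11,0
562,60,0,9,0
563,44,0,6,0
564,41,0,2,0
565,41,2,0,0
566,54,1,5,0
567,35,0,0,0
568,45,0,1,0
569,44,0,2,0
570,40,2,6,0
572,46,0,9,0
573,37,0,0,0
574,49,1,1,0
575,45,0,4,0
576,45,0,3,0
577,41,0,8,0
578,44,1,11,0
580,51,2,5,0
581,50,0,0,0
582,50,0,1,0
583,42,0,2,0
584,40,1,9,0
585,61,0,2,0
586,59,0,0,0
587,45,1,1,0
588,43,0,11,0
589,43,0,2,0
590,55,1,2,0
591,59,0,2,0
593,53,0,1,0
595,37,0,15,0
596,57,3,2,0
597,31,0,23,0
598,47,0,4,0
599,33,0,3,0
600,53,0,0,0
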