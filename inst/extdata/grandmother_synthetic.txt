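The Grandmother (a synthetic stand-in text for storage experiments)

In the last house of the lane, where the hedges grew tall and the swallows
nested under the eaves, there lived an old grandmother with silver hair and
mild grey eyes. Her hands were thin and folded like paper, and on her lap
lay a hymn book with a pressed rose between its leaves. The rose was dry
and faded now, yet she looked at it often, and her eyes grew bright, and
sometimes a tear slid down her cheek and fell upon the page.

The children of the house loved her dearly. In the evening they gathered
at her chair, and she told them of the days long gone: of lanes that rang
with song at harvest, of winters when the river froze so hard that carts
drove over it, of a garden where she had walked as a young girl with
ribbons in her hair. When she spoke, the old days rose up warm and golden,
and the children saw them as if through clear water.

"Tell us of the rose," the youngest would beg, and the grandmother would
smile and shake her head, and tell instead of the fair on the green, of
fiddlers and gingerbread and lanterns in the trees. But one evening, when
the fire burned low and the wind walked round the house, she opened the
hymn book and lifted the rose upon her palm.

"There was a student once," she said, "with eyes like deep water. He gave
me this rose on a morning in June, when the dew was still on the hedges.
We were to meet again when the summer turned. But the sea wanted sailors
that year, and the ship that took him never came home. The rose stayed
with me. It has been young with me, and it has grown old with me, and of
the two of us it has kept its promise best: it has never changed toward
me, only faded a little, as all faithful things fade."

The children were very still. The eldest laid her hand upon the
grandmother's hand, and the fire settled, and far off a dog barked twice
and was quiet. "Are you sad, grandmother?" asked the boy. "No," she said,
"not sad. When you are old, memory is a lamp, not a wound. It burns
steady, and by its light I can see every face I ever loved, and not one
of them is lost to me."

She let the rose fall back between the pages and closed the book upon it,
and the clasp clicked softly, like a door shutting on a warm room.

That night the moon stood round and white above the lane, and the
grandmother sat long at the window in her chair. The children slept; the
house breathed slowly around her. She thought of the June morning, of the
dew on the hedges, of the promise of the turning summer, and she was not
sorrowful, for it seemed to her that nothing that is truly kept in the
heart is ever taken away. The clock on the stair counted the hours, and
she heard it and did not mind it, for time is gentle to those who are at
peace with it.

In the morning the children came down early, and the sunlight lay across
the floor in long bright bars. The grandmother sat in her chair as if she
slept, with the hymn book on her lap and her hand resting on its cover.
They spoke to her softly, and she did not answer; and the eldest
understood, and opened the window wide, as one does for a traveller
setting out. The swallows were loud under the eaves, and the garden was
full of morning.

They buried her on the hill above the river, where the wind moves in the
long grass and the town lies small and far below. The hymn book they laid
beneath her folded hands, as she had asked, and the rose went with it,
keeping its promise to the last. And when the children grew and had
children of their own, they told them of the grandmother in the last house
of the lane: how her stories made the old days shine, how her lamp of
memory burned steady to the end, and how nothing loved is ever lost, but
only laid away, as a rose is laid between the leaves of a book, to be
found again entire.

So the story passed from hand to hand like a small warm coin, and the
house by the hedges kept its swallows, and the lane kept its name, and the
years went over them all as clouds go over a field, darkening nothing for
long. Whoever reads this far has read the whole of the keepsake text; it
ends here, complete.
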